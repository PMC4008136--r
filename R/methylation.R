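#' Filter CpG calls by read coverage
#'
#' Retains exactly the calls with `coverage >= min_coverage`. Poorly
#' covered CpGs carry unreliable methylation estimates, so both the
#' entropy statistic and the read-count test work on this filtered set.
#'
#' @param calls data.frame of per-CpG calls (`chrom, pos, coverage,
#'   methylated_reads, replica_id, cell_line`).
#' @param min_coverage minimum read depth (default 10).
#' @return the filtered data.frame.
#' @export
filter_coverage <- function(calls, min_coverage = 10) {
  out <- calls[calls$coverage >= min_coverage, , drop = FALSE]
  rownames(out) <- NULL
  out
}

islands_granges <- function(islands) {
  GenomicRanges::GRanges(islands$chrom,
                         IRanges::IRanges(start = islands$start + 1L,
                                          end = islands$end))
}

#' Per-island, per-sample mean methylation matrix
#'
#' Assigns coverage-filtered CpGs to islands (0-based half-open
#' intervals) and computes, per island and per sample (cell line x
#' replica), the unweighted mean over qualifying CpGs of
#' `methylated_reads / coverage`. The mean is over CpG fractions, not
#' the pooled read fraction: read-depth weighting is the read-count
#' test's job, not the level estimate's. Islands with no qualifying CpG
#' in a sample get `NA` there.
#'
#' @param calls coverage-filtered calls (see [filter_coverage()]),
#'   possibly spanning several cell lines and replicas.
#' @param islands CGI track data.frame.
#' @return list of class `"meth_matrix"` with elements `levels` (islands
#'   x samples matrix of mean methylation, `NA` when unsupported),
#'   `n_cpg` (supporting CpG counts), `meth_reads` and `total_reads`
#'   (summed read counts, the read-count test's input). Sample columns
#'   are named `<cell_line>.rep<replica_id>`.
#' @export
cgi_mean_methylation <- function(calls, islands) {
  if (nrow(islands) == 0) stop("island list is empty")
  sample_id <- paste0(calls$cell_line, ".rep", calls$replica_id)
  samples <- sort(unique(sample_id))
  ids <- islands$island_id

  gr_cpg <- GenomicRanges::GRanges(calls$chrom,
                                   IRanges::IRanges(start = calls$pos + 1L,
                                                    width = 1L))
  hits <- GenomicRanges::findOverlaps(gr_cpg, islands_granges(islands))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)

  f <- list(island = factor(si, levels = seq_len(nrow(islands)), labels = ids),
            sample = factor(sample_id[qi], levels = samples))
  frac <- calls$methylated_reads[qi] / calls$coverage[qi]
  out <- list(levels = tapply(frac, f, mean),
              n_cpg = tapply(frac, f, length),
              meth_reads = tapply(calls$methylated_reads[qi], f, sum),
              total_reads = tapply(calls$coverage[qi], f, sum))
  out$n_cpg[is.na(out$n_cpg)] <- 0
  class(out) <- "meth_matrix"
  out
}

#' Restrict a methylation matrix to selected samples
#'
#' @param mat a `"meth_matrix"`.
#' @param samples column names to keep.
#' @return a `"meth_matrix"` with the selected columns.
#' @export
subset_samples <- function(mat, samples) {
  stopifnot(all(samples %in% colnames(mat$levels)))
  out <- lapply(unclass(mat), function(m) m[, samples, drop = FALSE])
  class(out) <- "meth_matrix"
  out
}

#' Islands supported in every sample of a matrix
#'
#' The per-cell-line analysis universe is the set of islands with
#' methylation data in both replicas; across cell lines the "global
#' intersection universe" (islands present in all cell lines) feeds the
#' overlap null and the inter-cell-line analysis.
#'
#' @param mat a `"meth_matrix"`.
#' @return character vector of island ids with no `NA` entry.
#' @export
complete_islands <- function(mat) {
  rownames(mat$levels)[stats::complete.cases(mat$levels)]
}

#' Pearson correlation between the two replicas of a cell line
#'
#' @param mat a `"meth_matrix"` with exactly two sample columns.
#' @return Pearson r over islands non-missing in both replicas.
#' @export
replica_correlation <- function(mat) {
  stopifnot(ncol(mat$levels) == 2)
  keep <- stats::complete.cases(mat$levels)
  if (sum(keep) < 3)
    stop("replica correlation undefined: fewer than 3 common islands")
  stats::cor(mat$levels[keep, 1], mat$levels[keep, 2])
}
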