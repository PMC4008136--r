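#' Aggregate methylated / unmethylated read counts per island
#'
#' For each island and replica, sums methylated reads and unmethylated
#' reads (`coverage - methylated_reads`) over the coverage-qualifying
#' CpGs, producing the 2x2 table the read-count test operates on. The
#' aggregate reflects both read depth and CpG content, which is exactly
#' what the island-level significance test must account for. Islands
#' with no qualifying CpG in either replica are excluded.
#'
#' @param calls coverage-filtered calls for one cell line, both
#'   replicas (see [filter_coverage()]).
#' @param islands CGI track data.frame.
#' @return data.frame `region, meth_rep1, unmeth_rep1, meth_rep2,
#'   unmeth_rep2`.
#' @export
aggregate_counts <- function(calls, islands) {
  stopifnot(length(unique(calls$cell_line)) <= 1)
  mat <- cgi_mean_methylation(calls, islands)
  if (ncol(mat$levels) != 2)
    stop("expected exactly two replicas, found ", ncol(mat$levels))
  keep <- mat$n_cpg[, 1] > 0 & mat$n_cpg[, 2] > 0
  data.frame(region = rownames(mat$levels)[keep],
             meth_rep1 = mat$meth_reads[keep, 1],
             unmeth_rep1 = mat$total_reads[keep, 1] - mat$meth_reads[keep, 1],
             meth_rep2 = mat$meth_reads[keep, 2],
             unmeth_rep2 = mat$total_reads[keep, 2] - mat$meth_reads[keep, 2],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-sided Fisher exact test on a 2x2 read-count table
#'
#' Rows are replicas, columns methylated / unmethylated read counts.
#' Two-sided p-value by the point-probability rule (the sum of
#' hypergeometric point masses not exceeding the observed table's).
#'
#' @param tab 2x2 non-negative integer matrix with positive row sums.
#' @return the p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2), all(tab >= 0))
  if (any(rowSums(tab) == 0)) stop("both row sums must be positive")
  stats::fisher.test(tab)$p.value
}

#' Read-count (HBA) test over all islands of a cell line
#'
#' Fisher exact test per island on the aggregated 2x2 read-count
#' tables, with Benjamini-Hochberg FDR across all tested islands of the
#' cell line; an island is significant when its q-value is at most
#' `alpha`.
#'
#' @param counts output of [aggregate_counts()].
#' @param alpha FDR threshold (default 0.05).
#' @return data.frame `region, meth_rep1, unmeth_rep1, meth_rep2,
#'   unmeth_rep2, p_value, q_value, is_significant`.
#' @export
hba_filter <- function(counts, alpha = 0.05) {
  if (nrow(counts) < 1) stop("no testable regions")
  p <- vapply(seq_len(nrow(counts)), function(i)
    fisher_exact_2x2(matrix(c(counts$meth_rep1[i], counts$unmeth_rep1[i],
                              counts$meth_rep2[i], counts$unmeth_rep2[i]),
                            2, 2, byrow = TRUE)),
    numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  cbind(counts, data.frame(p_value = p, q_value = q,
                           is_significant = q <= alpha))
}
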