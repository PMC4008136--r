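#' Intersect entropy and read-count calls into the replica-difference
#' set
#'
#' An island is inter-replica differentially methylated (IRDM) in a
#' cell line when both the entropy statistic and the read-count test
#' call it: the intersection takes the absolute methylation difference,
#' the read coverage and the CpG content into account simultaneously.
#'
#' @param qdmr_calls data.frame from [call_dmr()] for one cell line.
#' @param hba_results data.frame from [hba_filter()] for the same cell
#'   line. Regions must come from the same universe (the entropy call
#'   universe must contain every tested region).
#' @return character vector of IRDM island ids.
#' @export
call_irdm <- function(qdmr_calls, hba_results) {
  if (!all(hba_results$region %in% qdmr_calls$region))
    stop("region universe mismatch between entropy and read-count calls")
  q_set <- qdmr_calls$region[!is.na(qdmr_calls$is_dmr) & qdmr_calls$is_dmr]
  h_set <- hba_results$region[hba_results$is_significant]
  sort(intersect(q_set, h_set))
}

#' Overlap degree of each called island across cell lines
#'
#' The overlap degree of an island is the number of cell lines in which
#' it is called IRDM; the minimum of 1 corresponds to an island called
#' in a single cell line. The sum of degrees always equals the sum of
#' per-cell-line call-set sizes.
#'
#' @param call_sets named list (per cell line) of IRDM island-id
#'   vectors; at least 2 cell lines.
#' @return named integer vector of degrees over islands called at least
#'   once.
#' @export
overlap_degrees <- function(call_sets) {
  if (length(call_sets) < 2) stop("need at least 2 cell lines")
  tab <- table(unlist(lapply(call_sets, unique), use.names = FALSE))
  deg <- as.integer(tab)
  names(deg) <- names(tab)
  deg
}

#' Monte Carlo null for the cross-cell-line overlap of calls
#'
#' Under the null that any island is equally likely to be called in any
#' cell line, each simulation reassigns, per cell line, the same number
#' of IRDM labels uniformly at random (without replacement) over the
#' shared universe, preserving every per-cell-line call count exactly.
#' The observed split of called islands into singletons (degree 1) and
#' shared (degree >= 2) is compared with the simulation-aggregated
#' split by a two-sided Fisher exact test; summing counts over
#' simulations keeps the table integer-valued and stable.
#'
#' @param call_sets named list of per-cell-line IRDM id vectors,
#'   restricted to `universe`.
#' @param universe character vector: the global intersection universe
#'   (islands with data in every cell line).
#' @param n_sim number of simulations (default 100).
#' @param seed integer seed.
#' @return list with `observed` (degree table of the observed calls),
#'   `null_degrees` (n_sim x max-degree matrix of simulated degree
#'   counts), `observed_split` (degree-1 vs degree->=2 counts),
#'   `null_split` (summed over simulations), and `fisher_p`.
#' @export
monte_carlo_overlap_null <- function(call_sets, universe, n_sim = 100,
                                     seed = 1L) {
  if (n_sim < 1) stop("n_sim must be >= 1")
  call_sets <- lapply(call_sets, intersect, universe)
  n_cl <- length(call_sets)
  sizes <- lengths(call_sets)
  deg_obs <- overlap_degrees(call_sets)
  max_d <- n_cl
  tab_obs <- tabulate(deg_obs, nbins = max_d)

  set.seed(seed)
  null_degrees <- matrix(0L, n_sim, max_d,
                         dimnames = list(NULL, seq_len(max_d)))
  for (s in seq_len(n_sim)) {
    hits <- integer(length(universe))
    for (k in seq_len(n_cl)) {
      idx <- sample.int(length(universe), sizes[k])
      hits[idx] <- hits[idx] + 1L
    }
    null_degrees[s, ] <- tabulate(hits, nbins = max_d)
  }
  obs_split <- c(singleton = tab_obs[1], shared = sum(tab_obs[-1]))
  null_split <- c(singleton = sum(null_degrees[, 1]),
                  shared = sum(null_degrees[, -1, drop = FALSE]))
  p <- stats::fisher.test(rbind(obs_split, null_split))$p.value
  list(observed = tab_obs, null_degrees = null_degrees,
       observed_split = obs_split, null_split = null_split,
       fisher_p = p)
}

#' Common and most-common tiers of recurrently called islands
#'
#' "Common" islands are called in at least two cell lines. The
#' "most common" tier is the top of the autosomal common-degree
#' distribution: the cutoff is the smallest integer degree `d` such
#' that the fraction of autosomal common islands with degree >= `d` is
#' at most `percentile`; most-common islands are the autosomal common
#' islands at or above the cutoff. If no degree satisfies the mass
#' condition the cutoff exceeds the maximum degree and the tier is
#' empty; if all degrees are equal the tier is therefore all-or-none.
#'
#' @param degrees named integer vector from [overlap_degrees()].
#' @param chrom named character vector mapping island id to chromosome
#'   (must cover all called islands).
#' @param x_chrom name of the X-designated chromosome, excluded from
#'   the cutoff computation and the most-common tier.
#' @param percentile tail mass defining the most-common tier
#'   (default 0.05).
#' @return list with `common` (ids), `most_common` (ids), `cutoff`
#'   (integer degree or `Inf`).
#' @export
define_tiers <- function(degrees, chrom, x_chrom = "chrX",
                         percentile = 0.05) {
  stopifnot(all(names(degrees) %in% names(chrom)))
  common <- names(degrees)[degrees >= 2]
  auto_common <- common[chrom[common] != x_chrom]
  if (length(auto_common) == 0)
    return(list(common = common, most_common = character(0), cutoff = Inf))
  d <- degrees[auto_common]
  cutoff <- Inf
  for (cand in sort(unique(d))) {
    if (mean(d >= cand) <= percentile) { cutoff <- cand; break }
  }
  list(common = common,
       most_common = auto_common[d >= cutoff],
       cutoff = cutoff)
}
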