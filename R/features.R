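#' Bootstrap test of the chromosome distribution of a call set
#'
#' Compares the per-chromosome proportion of called islands with the
#' proportion expected from the universe, against a bootstrap null in
#' which the same number of islands is repeatedly sampled without
#' replacement from the universe. The empirical enrichment p-value uses
#' the `(1 + k) / (1 + n_boot)` estimator (never exactly 0), so with
#' `n_boot = 1e4` a chromosome never exceeded by any simulation reports
#' p just below 1e-4.
#'
#' @param irdm_ids character vector of called island ids (subset of the
#'   universe).
#' @param universe data.frame with `island_id` and `chrom` covering all
#'   chromosomes of interest.
#' @param n_boot number of bootstrap samples (default 1e4).
#' @param seed integer seed.
#' @return data.frame per chromosome: `chrom, observed_n,
#'   observed_prop, expected_prop, p_enrich, direction` (sign of the
#'   observed minus expected proportion).
#' @export
chromosome_bootstrap <- function(irdm_ids, universe, n_boot = 1e4,
                                 seed = 1L) {
  stopifnot(all(irdm_ids %in% universe$island_id))
  chroms <- sort(unique(universe$chrom))
  chrom_f <- factor(universe$chrom, levels = chroms)
  n_set <- length(irdm_ids)
  obs <- tabulate(chrom_f[universe$island_id %in% irdm_ids],
                  nbins = length(chroms))
  obs_prop <- obs / n_set
  exp_prop <- as.numeric(table(chrom_f)) / nrow(universe)

  set.seed(seed)
  exceed <- integer(length(chroms))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(universe), n_set)
    sim <- tabulate(chrom_f[idx], nbins = length(chroms)) / n_set
    exceed <- exceed + (sim >= obs_prop)
  }
  data.frame(chrom = chroms, observed_n = obs, observed_prop = obs_prop,
             expected_prop = exp_prop,
             p_enrich = (1 + exceed) / (1 + n_boot),
             direction = sign(obs_prop - exp_prop),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Strand-aware per-gene annotation intervals (0-based half-open) used
# by the gene-region classifier. For a plus-strand gene:
#   five_prime:  [cds_start - flank, end of first intron)
#   three_prime: [start of final intron, tx_end + flank)
#   intragenic:  the internal exons/introns between those two
#   near:        [tx_start - flank, tx_end + flank)  (catch-all strip)
# Minus-strand genes are mirrored. Single-exon genes have no introns:
# the five-prime region runs to the gene end and wins by precedence.
gene_region_intervals <- function(genes, flank = 3000) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    s <- as.integer(strsplit(genes$exon_starts[i], ",")[[1]])
    e <- as.integer(strsplit(genes$exon_ends[i], ",")[[1]])
    k <- length(s)
    txs <- genes$tx_start[i]; txe <- genes$tx_end[i]
    if (genes$strand[i] == "+") {
      tls <- genes$cds_start[i]
      five <- c(tls - flank, if (k >= 2) s[2] else txe)
      three <- c(if (k >= 2) e[k - 1] else txe, txe + flank)
    } else {
      tls <- genes$cds_end[i]
      five <- c(if (k >= 2) e[k - 1] else txs, tls + flank)
      three <- c(txs - flank, if (k >= 2) s[2] else txs)
    }
    mk <- function(cls, lo, hi) if (hi > lo)
      data.frame(chrom = genes$chrom[i], start = lo, end = hi,
                 class = cls, stringsAsFactors = FALSE) else NULL
    intra <- if (genes$strand[i] == "+")
      mk("intragenic", if (k >= 2) s[2] else txe,
         if (k >= 2) e[k - 1] else txe)
    else
      mk("intragenic", if (k >= 2) s[2] else txs,
         if (k >= 2) e[k - 1] else txs)
    rbind(mk("five_prime", five[1], five[2]),
          mk("three_prime", three[1], three[2]),
          intra,
          mk("near", txs - flank, txe + flank))
  })
  do.call(rbind, rows)
}

#' Classify islands into the four gene-region classes
#'
#' Each island is assigned exactly one of `five_prime`, `intragenic`,
#' `three_prime`, `intergenic` from the location of its midpoint,
#' strand-aware: the 5' class runs from `flank` bp upstream of the
#' translational start through the first intron; intragenic covers the
#' internal exons and introns; 3' covers the final intron and final
#' exon; islands at least `flank` bp away from every gene are
#' intergenic. When genes disagree the precedence is
#' 5' > 3' > intragenic. A midpoint within `flank` bp of a gene that
#' matches none of the in-gene rules (e.g. the short strip just
#' downstream of the 3' end) is assigned `three_prime`.
#'
#' @param islands CGI track data.frame.
#' @param genes gene-model data.frame; zero genes makes every island
#'   intergenic.
#' @param flank flanking distance in bp (default 3000).
#' @return factor of classes, one per island, named by island id.
#' @export
classify_gene_region <- function(islands, genes, flank = 3000) {
  lv <- c("five_prime", "intragenic", "three_prime", "intergenic")
  out <- factor(rep("intergenic", nrow(islands)), levels = lv)
  names(out) <- islands$island_id
  if (nrow(genes) == 0) return(out)
  iv <- gene_region_intervals(genes, flank)
  mid <- islands$start + (islands$end - islands$start) %/% 2
  gr_mid <- GenomicRanges::GRanges(islands$chrom,
                                   IRanges::IRanges(mid + 1L, width = 1L))
  gr_iv <- GenomicRanges::GRanges(iv$chrom,
                                  IRanges::IRanges(pmax(iv$start, 0) + 1L,
                                                   iv$end))
  hits <- GenomicRanges::findOverlaps(gr_mid, gr_iv)
  qh <- S4Vectors::queryHits(hits)
  cls <- iv$class[S4Vectors::subjectHits(hits)]
  for (i in unique(qh)) {
    c_i <- cls[qh == i]
    out[i] <- if ("five_prime" %in% c_i) "five_prime"
      else if ("three_prime" %in% c_i) "three_prime"
      else if ("intragenic" %in% c_i) "intragenic"
      else "three_prime"  # near a gene but matching no in-gene rule
  }
  out
}

#' Chi-square test of gene-region class composition
#'
#' Pearson chi-square of the called set's class counts against the
#' class proportions of all islands (the expected counts are the
#' all-island proportions scaled to the called set's size).
#'
#' @param classes_irdm factor of classes for the called set.
#' @param classes_all factor of classes for all islands.
#' @return list with `statistic`, `df`, `p_value`, `observed`,
#'   `expected`.
#' @export
gene_region_chisq <- function(classes_irdm, classes_all) {
  lv <- union(levels(classes_all), levels(classes_irdm))
  obs <- table(factor(classes_irdm, levels = lv))
  prop <- table(factor(classes_all, levels = lv)) / length(classes_all)
  keep <- prop > 0
  if (any(obs[!keep] > 0))
    stop("observed counts in a class with zero expected proportion")
  obs <- obs[keep]; prop <- prop[keep]
  expd <- prop * sum(obs)
  stat <- sum((obs - expd)^2 / expd)
  df <- length(obs) - 1
  list(statistic = as.numeric(stat), df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       observed = obs, expected = expd)
}

#' Welch t-tests of island structural features between two groups
#'
#' Two-sided Welch t-tests comparing G+C fraction, length and
#' observed/expected CpG ratio between the called set and the
#' remaining islands.
#'
#' @param irdm_islands,other_islands CGI track subsets (>= 2 rows
#'   each).
#' @param features columns to compare.
#' @return data.frame `feature, mean_irdm, mean_other, p_value`.
#' @export
structural_feature_tests <- function(irdm_islands, other_islands,
                                     features = c("gc_fraction", "length",
                                                  "obs_exp")) {
  stopifnot(nrow(irdm_islands) >= 2, nrow(other_islands) >= 2)
  rows <- lapply(features, function(f) {
    x <- irdm_islands[[f]]; y <- other_islands[[f]]
    p <- if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      warning("degenerate variance for feature ", f)
      if (mean(x) == mean(y)) 1 else 0
    } else stats::t.test(x, y)$p.value
    data.frame(feature = f, mean_irdm = mean(x), mean_other = mean(y),
               p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Call islands differentially methylated across cell lines
#'
#' Applies the adjusted-entropy statistic across N cell lines (one
#' methylation value per cell line, the mean of its two replicas) on
#' the global intersection universe, at the conservative null SD of
#' 0.015.
#'
#' @param cell_matrix islands x cell-lines matrix of methylation
#'   levels (>= 2 columns, no missing rows for tested islands).
#' @param sd null-simulation SD (default 0.015).
#' @param percentile threshold percentile (default 0.05).
#' @param n_sim null-simulation size (default 1e5).
#' @param seed integer seed.
#' @return character vector of island ids called inter-cell-line
#'   differential.
#' @export
call_icdm <- function(cell_matrix, sd = 0.015, percentile = 0.05,
                      n_sim = 1e5, seed = 1L) {
  if (ncol(cell_matrix) < 2) stop("need at least 2 cell lines")
  thr <- derive_threshold(ncol(cell_matrix), sd = sd,
                          percentile = percentile, n_sim = n_sim,
                          seed = seed)
  calls <- call_dmr(cell_matrix, thr)
  calls$region[!is.na(calls$is_dmr) & calls$is_dmr]
}

#' Enrichment of replica-difference calls among cross-cell-line calls
#'
#' For each tier of the replica-difference (IRDM) calls, a two-sided
#' Fisher exact test on the 2x2 table (in tier vs not) x (in the
#' cross-cell-line set vs not) over the shared universe. Degenerate
#' margins (e.g. the cross-cell-line set equals the universe) are
#' reported with `NA` p-value.
#'
#' @param tiers named list of island-id vectors (e.g. `all`, `common`,
#'   `most_common`).
#' @param icdm_ids island ids called differential across cell lines.
#' @param universe character vector: the shared universe.
#' @return data.frame `tier, n_tier, n_overlap, odds_ratio, p_value`.
#' @export
icdm_enrichment <- function(tiers, icdm_ids, universe) {
  stopifnot(all(icdm_ids %in% universe))
  rows <- lapply(names(tiers), function(nm) {
    set <- intersect(tiers[[nm]], universe)
    a <- length(intersect(set, icdm_ids))
    b <- length(set) - a
    c_ <- length(icdm_ids) - a
    d <- length(universe) - a - b - c_
    tab <- matrix(c(a, b, c_, d), 2, 2, byrow = TRUE)
    degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
    ft <- if (degenerate) list(estimate = NA_real_, p.value = NA_real_)
      else stats::fisher.test(tab)
    data.frame(tier = nm, n_tier = length(set), n_overlap = a,
               odds_ratio = unname(ft$estimate), p_value = ft$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Welch one-way test of per-cell-line call counts across groups
#'
#' Welch's analysis of means (unequal variances) of the per-cell-line
#' number of called islands across cell-type groups (e.g. cancer, EBV,
#' normal). With zero variance in every group the statistic is
#' undefined and `NA` is returned (with a warning).
#'
#' @param counts numeric vector of per-cell-line call counts.
#' @param groups factor/character of group labels (>= 2 groups, each
#'   with >= 2 cell lines).
#' @return the p-value.
#' @export
welch_group_test <- function(counts, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs >= 2 cell lines")
  v <- tapply(counts, groups, stats::var)
  if (all(v == 0)) {
    warning("zero variance in every group; p undefined")
    return(NA_real_)
  }
  stats::oneway.test(counts ~ groups, var.equal = FALSE)$p.value
}
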