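#' Run the full inter-replica differential-methylation pipeline
#'
#' End-to-end analysis on a synthetic dataset: generate the CGI track
#' and paired-replica reads, filter CpGs by coverage, build per-cell-line
#' methylation matrices, call differential islands by the adjusted
#' entropy (null threshold at `sd_qdmr`) and the read-count Fisher test
#' (BH FDR at `alpha`), intersect them into per-cell-line IRDM sets,
#' compute overlap degrees and tiers, run the Monte Carlo overlap null
#' on the global intersection universe, bootstrap the chromosome
#' distribution of the common tier, test structural features, and call
#' inter-cell-line differential islands at `sd_icdm` with tier
#' enrichment.
#'
#' @param config a [sim_config()].
#' @param min_coverage CpG coverage filter (default 10).
#' @param sd_qdmr null SD for the two-replica entropy threshold
#'   (default 0.03).
#' @param sd_icdm null SD for the inter-cell-line call (default 0.015).
#' @param alpha significance level for the read-count FDR (default
#'   0.05).
#' @param n_sim_threshold null-simulation size for thresholds (default
#'   1e5).
#' @param n_mc Monte Carlo overlap simulations (default 100).
#' @param n_boot chromosome bootstrap samples (default 1e4).
#' @param seed integer seed for the analysis randomness (thresholds,
#'   nulls, bootstrap); data randomness is governed by `config$seed`.
#' @return list with the generated data, per-cell-line results and all
#'   summary reports (see the methods vignette for a walk-through).
#' @export
run_irdm_pipeline <- function(config = sim_config(), min_coverage = 10,
                              sd_qdmr = 0.03, sd_icdm = 0.015,
                              alpha = 0.05, n_sim_threshold = 1e5,
                              n_mc = 100, n_boot = 1e4, seed = 1L) {
  track <- generate_cgi_track(config)
  sim <- generate_replica_reads(track, config)
  calls <- filter_coverage(sim$calls, min_coverage)
  mat <- cgi_mean_methylation(calls, track)

  cells <- sort(unique(sim$calls$cell_line))
  thr <- derive_threshold(2, sd = sd_qdmr, n_sim = n_sim_threshold,
                          seed = seed)

  per_cell <- lapply(cells, function(cl) {
    cols <- paste0(cl, ".rep", 1:2)
    m_cl <- subset_samples(mat, cols)
    universe <- complete_islands(m_cl)
    qdmr <- call_dmr(m_cl$levels[universe, , drop = FALSE], thr)
    counts <- aggregate_counts(calls[calls$cell_line == cl, , drop = FALSE],
                               track)
    counts <- counts[counts$region %in% universe, , drop = FALSE]
    hba <- hba_filter(counts, alpha)
    list(cell_line = cl, universe = universe,
         correlation = replica_correlation(m_cl),
         qdmr = qdmr, hba = hba, irdm = call_irdm(qdmr, hba))
  })
  names(per_cell) <- cells
  irdm_sets <- lapply(per_cell, `[[`, "irdm")

  # global intersection universe: islands with data in every sample
  universe_global <- complete_islands(mat)
  degrees <- overlap_degrees(irdm_sets)
  chrom_map <- stats::setNames(track$chrom, track$island_id)
  tiers <- define_tiers(degrees, chrom_map, x_chrom = config$x_chrom)
  mc <- monte_carlo_overlap_null(irdm_sets, universe_global,
                                 n_sim = n_mc, seed = seed + 1L)

  called_any <- names(degrees)
  boot <- chromosome_bootstrap(
    intersect(tiers$common, universe_global),
    track[track$island_id %in% universe_global,
          c("island_id", "chrom"), drop = FALSE],
    n_boot = n_boot, seed = seed + 2L)

  common_auto <- tiers$common[chrom_map[tiers$common] != config$x_chrom]
  other_auto <- setdiff(track$island_id[track$chrom != config$x_chrom],
                        tiers$common)
  feats <- structural_feature_tests(
    track[track$island_id %in% common_auto, , drop = FALSE],
    track[track$island_id %in% other_auto, , drop = FALSE])

  # inter-cell-line calling on the intersection universe (autosomes)
  auto_universe <- universe_global[chrom_map[universe_global] != config$x_chrom]
  cell_mat <- sapply(cells, function(cl)
    rowMeans(mat$levels[auto_universe, paste0(cl, ".rep", 1:2),
                        drop = FALSE]))
  icdm <- call_icdm(cell_mat, sd = sd_icdm, n_sim = n_sim_threshold,
                    seed = seed + 3L)
  icdm_enr <- icdm_enrichment(
    list(all = intersect(called_any, auto_universe),
         common = intersect(tiers$common, auto_universe),
         most_common = intersect(tiers$most_common, auto_universe)),
    icdm, auto_universe)

  list(config = config, track = track, ground_truth = sim$ground_truth,
       matrix = mat, threshold = thr, per_cell = per_cell,
       irdm_sets = irdm_sets, degrees = degrees, tiers = tiers,
       universe_global = universe_global, mc_overlap = mc,
       chrom_bootstrap = boot, structural_tests = feats,
       icdm = icdm, icdm_enrichment = icdm_enr)
}

#' Sensitivity and empirical FDR of the calls against ground truth
#'
#' @param irdm_sets named list of per-cell-line called id sets.
#' @param ground_truth as returned by [generate_replica_reads()].
#' @return list with pooled `sensitivity` (recovered planted / planted)
#'   and `fdr` (false calls / calls) over all cell lines.
#' @export
recovery_stats <- function(irdm_sets, ground_truth) {
  tp <- 0; fp <- 0; fn <- 0
  for (cl in names(irdm_sets)) {
    truth <- ground_truth$planted[[cl]]
    called <- irdm_sets[[cl]]
    tp <- tp + length(intersect(called, truth))
    fp <- fp + length(setdiff(called, truth))
    fn <- fn + length(setdiff(truth, called))
  }
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       fdr = if (tp + fp > 0) fp / (tp + fp) else NA_real_)
}
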