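#' Simulation configuration for the synthetic RRBS-like generator
#'
#' Builds and validates the configuration object consumed by
#' [generate_cgi_track()], [generate_replica_reads()],
#' [generate_gene_models()] and [generate_expression()].
#'
#' The defaults describe the study conditions the package is exercised
#' under: 5 cell lines, 2000 CpG islands (CGIs) spread over five autosomes
#' plus an X chromosome, per-CpG read depth that is negative-binomially
#' overdispersed around 30x, per-CpG biological noise with SD 0.03 on the
#' methylation fraction, and 5% of islands planted as truly differential
#' between the two replicas with an absolute methylation shift of 0.4.
#' Planting is "shared": a global pool of susceptible islands is drawn
#' first (biased towards the X chromosome) and each cell line takes 80%
#' of its planted set from that pool, so the same islands recur across
#' cell lines. Susceptible islands carry structural biases (lower G+C,
#' shorter length, lower observed/expected CpG ratio), mirroring the
#' features the downstream characterisation stage is designed to detect.
#'
#' @param n_cell_lines number of simulated cell lines.
#' @param n_cgis total number of CGIs across all chromosomes.
#' @param chromosome_layout named integer vector mapping chromosome name
#'   to CGI count; must sum to `n_cgis` and include one X-designated
#'   chromosome. `NULL` distributes `n_cgis` over chr1-chr5 and chrX
#'   with fixed proportions.
#' @param x_chrom name of the X-designated chromosome.
#' @param cpgs_per_cgi list with `mean` and `min`: CpG count per island is
#'   Poisson(`mean`) floored at `min` and capped at `length/2`.
#' @param coverage list with `mean` and `dispersion` of the negative
#'   binomial per-CpG read depth (`dispersion` is the NB size parameter).
#' @param biological_sd SD of the per-CpG, per-replica Gaussian noise
#'   added to the true methylation fraction (clipped to `[0,1]`).
#' @param planted_irdm_fraction fraction of CGIs made truly differential
#'   between the two replicas of each cell line.
#' @param planted_shift absolute methylation difference between replicas
#'   for planted islands, in `(0,1]`.
#' @param shared_planting logical; draw planted islands mostly from a
#'   global susceptible pool shared across cell lines?
#' @param shared_fraction fraction of each cell line's planted set taken
#'   from the shared pool when `shared_planting` is `TRUE`.
#' @param planting_chrom_bias named numeric vector of sampling-weight
#'   multipliers applied per chromosome when drawing the susceptible
#'   pool (e.g. `c(chrX = 8)`).
#' @param feature_bias list of structural shifts applied to susceptible
#'   islands: additive `gc_fraction` and `obs_exp` shifts and a
#'   multiplicative `length_factor`.
#' @param cell_line_sd SD of the per-cell-line jitter of island base
#'   methylation (all islands).
#' @param unstable_cell_line_sd extra per-cell-line jitter SD for
#'   susceptible-pool islands, making them differential across cell
#'   lines as well as between replicas.
#' @param expression_dr_shift extra log-scale replica divergence applied
#'   to the expression of genes whose regulatory domain intersects a
#'   susceptible island (0 = no transcriptional effect).
#' @param n_genes number of simulated gene models.
#' @param expression list with `meanlog`, `sdlog` (log-normal expression
#'   level) and `replica_cv` (log-scale SD between replicas).
#' @param seed integer seed; identical seed + config give byte-identical
#'   outputs from every generator.
#'
#' @return a validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_cell_lines = 5,
                       n_cgis = 2000,
                       chromosome_layout = NULL,
                       x_chrom = "chrX",
                       cpgs_per_cgi = list(mean = 20, min = 4),
                       coverage = list(mean = 30, dispersion = 5),
                       biological_sd = 0.03,
                       planted_irdm_fraction = 0.05,
                       planted_shift = 0.4,
                       shared_planting = TRUE,
                       shared_fraction = 0.8,
                       planting_chrom_bias = c(chrX = 8),
                       feature_bias = list(gc_fraction = -0.02,
                                           length_factor = 0.65,
                                           obs_exp = -0.05),
                       cell_line_sd = 0.05,
                       unstable_cell_line_sd = 0.2,
                       expression_dr_shift = 0,
                       n_genes = 300,
                       expression = list(meanlog = 3, sdlog = 1,
                                         replica_cv = 0.2),
                       seed = 1L) {
  if (is.null(chromosome_layout)) {
    props <- c(chr1 = 0.25, chr2 = 0.225, chr3 = 0.2, chr4 = 0.175,
               chr5 = 0.075, chrX = 0.075)
    chromosome_layout <- round(props * n_cgis)
    chromosome_layout[1] <- n_cgis - sum(chromosome_layout[-1])
  }
  if (length(chromosome_layout) == 0 || any(chromosome_layout < 0) ||
      is.null(names(chromosome_layout)) || anyDuplicated(names(chromosome_layout)))
    stop("chromosome_layout must be a named vector of non-negative counts ",
         "with unique chromosome names")
  if (sum(chromosome_layout) != n_cgis)
    stop("chromosome_layout must sum to n_cgis (", n_cgis, "), got ",
         sum(chromosome_layout))
  if (!x_chrom %in% names(chromosome_layout))
    stop("chromosome_layout must include the X-designated chromosome '",
         x_chrom, "'")
  stopifnot(n_cell_lines >= 1,
            planted_irdm_fraction >= 0, planted_irdm_fraction <= 1,
            planted_shift > 0, planted_shift <= 1,
            biological_sd >= 0,
            shared_fraction >= 0, shared_fraction <= 1,
            coverage$mean > 0, coverage$dispersion > 0,
            cpgs_per_cgi$mean >= 1, cpgs_per_cgi$min >= 1)
  cfg <- list(n_cell_lines = as.integer(n_cell_lines),
              n_cgis = as.integer(n_cgis),
              chromosome_layout = chromosome_layout,
              x_chrom = x_chrom,
              cpgs_per_cgi = cpgs_per_cgi,
              coverage = coverage,
              biological_sd = biological_sd,
              planted_irdm_fraction = planted_irdm_fraction,
              planted_shift = planted_shift,
              shared_planting = isTRUE(shared_planting),
              shared_fraction = shared_fraction,
              planting_chrom_bias = planting_chrom_bias,
              feature_bias = feature_bias,
              cell_line_sd = cell_line_sd,
              unstable_cell_line_sd = unstable_cell_line_sd,
              expression_dr_shift = expression_dr_shift,
              n_genes = as.integer(n_genes),
              expression = expression,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

clip01 <- function(x) pmin(1, pmax(0, x))
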