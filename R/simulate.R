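#' Generate a synthetic CpG-island annotation track
#'
#' Lays out non-overlapping, sorted islands (0-based half-open
#' coordinates) on the chromosomes of `config$chromosome_layout`, with
#' structural fields mimicking a UCSC-style CGI track: length, CpG
#' count, G+C fraction and observed/expected CpG ratio. A pool of
#' "susceptible" islands is drawn (chromosome-biased per
#' `planting_chrom_bias`) and receives the structural shifts in
#' `feature_bias`; downstream, [generate_replica_reads()] plants the
#' differential signal preferentially on this pool. The pool ids are
#' attached as `attr(track, "susceptible_ids")`.
#'
#' Structural baselines (G+C 0.697 +/- 0.03, length log-normal with
#' median ~830 bp, obs/exp 0.84 +/- 0.08) match typical human CGI
#' annotation summaries.
#'
#' @param config a [sim_config()] object.
#' @return data.frame with columns `chrom, start, end, island_id,
#'   length, cpg_count, gc_fraction, obs_exp`, sorted by chromosome and
#'   start.
#' @export
generate_cgi_track <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  layout <- config$chromosome_layout
  if (length(layout) == 0) stop("empty chromosome layout")
  set.seed(config$seed + 1L)

  rows <- lapply(names(layout), function(chr) {
    n <- layout[[chr]]
    if (n == 0) return(NULL)
    len <- pmin(3000, pmax(200, round(stats::rlnorm(n, log(830), 0.45))))
    gap <- round(stats::rexp(n, 1 / 20000)) + 2000L
    start <- cumsum(gap) + cumsum(c(0L, len[-n]))
    data.frame(chrom = chr, start = start, end = start + len,
               stringsAsFactors = FALSE)
  })
  track <- do.call(rbind, rows)
  ord <- order(track$chrom, track$start)
  track <- track[ord, , drop = FALSE]
  track$island_id <- sprintf("cgi_%05d", seq_len(nrow(track)))
  track$gc_fraction <- clip01(stats::rnorm(nrow(track), 0.697, 0.03))
  track$obs_exp <- pmax(0.2, stats::rnorm(nrow(track), 0.84, 0.08))

  # susceptible pool: size = one cell line's planted quota
  n_pool <- round(config$planted_irdm_fraction * config$n_cgis)
  w <- rep(1, nrow(track))
  for (chr in names(config$planting_chrom_bias))
    w[track$chrom == chr] <- config$planting_chrom_bias[[chr]]
  pool <- if (n_pool > 0)
    sample(track$island_id, n_pool, prob = w / sum(w)) else character(0)
  sus <- track$island_id %in% pool

  fb <- config$feature_bias
  if (!is.null(fb$length_factor) && any(sus)) {
    newlen <- pmax(200, round((track$end - track$start)[sus] * fb$length_factor))
    track$end[sus] <- track$start[sus] + newlen
  }
  if (!is.null(fb$gc_fraction))
    track$gc_fraction[sus] <- clip01(track$gc_fraction[sus] + fb$gc_fraction)
  if (!is.null(fb$obs_exp))
    track$obs_exp[sus] <- pmax(0.1, track$obs_exp[sus] + fb$obs_exp)

  track$length <- track$end - track$start
  k <- stats::rpois(nrow(track), config$cpgs_per_cgi$mean)
  track$cpg_count <- pmin(floor(track$length / 2),
                          pmax(config$cpgs_per_cgi$min, k))
  track <- track[, c("chrom", "start", "end", "island_id", "length",
                     "cpg_count", "gc_fraction", "obs_exp")]
  rownames(track) <- NULL
  attr(track, "susceptible_ids") <- sort(pool)
  track
}

#' Deterministic CpG positions for an island
#'
#' CpGs are evenly spaced inside the island so that the same genome
#' underlies every cell line and replica. 0-based positions of the C.
#'
#' @param start,end island coordinates (0-based half-open).
#' @param k number of CpGs.
#' @return integer vector of length `k`, strictly increasing, in
#'   `[start, end - 2]`.
#' @export
cpg_positions <- function(start, end, k) {
  len <- end - start
  pos <- start + floor((seq_len(k) - 0.5) / k * len)
  pmin(pos, end - 2L)
}

#' Generate paired-replica per-CpG methylation reads for all cell lines
#'
#' For every island a base methylation level mu is drawn from a bimodal
#' mixture (low ~0.05 / high ~0.9, mimicking the U-shaped marginal of
#' real CGI methylation) and jittered per cell line. For non-planted
#' islands both replicas share the cell line's mu; for planted islands
#' the two replicas' true levels differ by exactly
#' `config$planted_shift`. Each CpG's per-replica level is
#' `clip(mu_rep + N(0, biological_sd), 0, 1)`; its coverage is negative
#' binomial and its methylated-read count binomial given coverage and
#' level.
#'
#' @param track output of [generate_cgi_track()].
#' @param config the same [sim_config()] used for the track.
#' @return list with `calls` (data.frame: `chrom, pos, coverage,
#'   methylated_reads, replica_id, cell_line`) and `ground_truth` (list:
#'   `planted` named list of planted island ids per cell line,
#'   `pool_ids`, `mu` base levels, `true_levels` per cell line a
#'   2-column matrix of per-replica true island levels).
#' @export
generate_replica_reads <- function(track, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  n <- nrow(track)
  ids <- track$island_id
  pool <- attr(track, "susceptible_ids")
  if (is.null(pool)) pool <- character(0)
  is_pool <- ids %in% pool

  hi <- stats::rbinom(n, 1, 0.5) == 1
  mu <- ifelse(hi, stats::rbeta(n, 27, 3), stats::rbeta(n, 2, 38))

  n_planted <- round(config$planted_irdm_fraction * n)
  delta <- config$planted_shift
  kmat <- track$cpg_count
  pos_list <- lapply(seq_len(n), function(i)
    cpg_positions(track$start[i], track$end[i], kmat[i]))
  n_cpg_total <- sum(kmat)
  chrom_rep <- rep(track$chrom, kmat)
  pos_rep <- unlist(pos_list, use.names = FALSE)
  island_idx <- rep(seq_len(n), kmat)

  cells <- sprintf("cell_%02d", seq_len(config$n_cell_lines))
  planted <- stats::setNames(vector("list", length(cells)), cells)
  true_levels <- stats::setNames(vector("list", length(cells)), cells)
  out <- vector("list", length(cells) * 2)

  for (ci in seq_along(cells)) {
    jit <- stats::rnorm(n, 0, config$cell_line_sd) +
      ifelse(is_pool, stats::rnorm(n, 0, config$unstable_cell_line_sd), 0)
    mu_c <- clip01(mu + jit)

    if (n_planted > 0) {
      if (config$shared_planting && length(pool) > 0) {
        n_sh <- min(round(config$shared_fraction * n_planted), length(pool))
        sel <- c(sample(pool, n_sh),
                 sample(setdiff(ids, pool), n_planted - n_sh))
      } else {
        sel <- sample(ids, n_planted)
      }
    } else sel <- character(0)
    planted[[ci]] <- sort(sel)
    is_pl <- ids %in% sel

    lo <- pmin(pmax(mu_c - delta / 2, 0), 1 - delta)
    swap <- stats::rbinom(n, 1, 0.5) == 1
    mu1 <- ifelse(is_pl, ifelse(swap, lo + delta, lo), mu_c)
    mu2 <- ifelse(is_pl, ifelse(swap, lo, lo + delta), mu_c)
    true_levels[[ci]] <- cbind(rep1 = mu1, rep2 = mu2)

    for (rep_id in 1:2) {
      mu_rep <- if (rep_id == 1) mu1 else mu2
      lev <- clip01(stats::rnorm(n_cpg_total, mu_rep[island_idx],
                                 config$biological_sd))
      cov <- stats::rnbinom(n_cpg_total, size = config$coverage$dispersion,
                            mu = config$coverage$mean)
      meth <- stats::rbinom(n_cpg_total, cov, lev)
      out[[(ci - 1) * 2 + rep_id]] <- data.frame(
        chrom = chrom_rep, pos = pos_rep, coverage = cov,
        methylated_reads = meth, replica_id = rep_id,
        cell_line = cells[ci], stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, out)
  rownames(calls) <- NULL
  list(calls = calls,
       ground_truth = list(planted = planted, pool_ids = pool, mu = mu,
                           true_levels = true_levels,
                           island_id = ids))
}

#' Generate synthetic gene models
#'
#' Non-overlapping multi-exon genes on the same chromosomes as the CGI
#' track, with random strand, a translational start inside the
#' transcript, and sorted non-overlapping exons.
#'
#' @param config a [sim_config()] object.
#' @return data.frame with columns `gene_id, chrom, strand, tx_start,
#'   tx_end, cds_start, cds_end, exon_starts, exon_ends` (exon columns
#'   are comma-separated 0-based half-open coordinates). `cds_start` /
#'   `cds_end` bound the coding span; the translational start is
#'   `cds_start` on `+` genes and `cds_end` on `-` genes.
#' @export
generate_gene_models <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  if (config$n_genes == 0) {
    return(data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), tx_start = integer(0),
                      tx_end = integer(0), cds_start = integer(0),
                      cds_end = integer(0), exon_starts = character(0),
                      exon_ends = character(0), stringsAsFactors = FALSE))
  }
  chroms <- names(config$chromosome_layout)
  n_per <- table(factor(sample(chroms, config$n_genes, replace = TRUE,
                               prob = config$chromosome_layout + 1),
                        levels = chroms))
  rows <- lapply(chroms, function(chr) {
    m <- n_per[[chr]]
    if (m == 0) return(NULL)
    len <- round(stats::runif(m, 5000, 60000))
    gap <- round(stats::rexp(m, 1 / 40000)) + 8000L
    start <- cumsum(gap) + cumsum(c(0L, len[-m]))
    df <- data.frame(chrom = chr, tx_start = start, tx_end = start + len,
                     strand = sample(c("+", "-"), m, replace = TRUE),
                     stringsAsFactors = FALSE)
    df
  })
  genes <- do.call(rbind, rows)
  genes <- genes[order(genes$chrom, genes$tx_start), , drop = FALSE]
  genes$gene_id <- sprintf("gene_%04d", seq_len(nrow(genes)))

  ex <- lapply(seq_len(nrow(genes)), function(i) {
    s <- genes$tx_start[i]; e <- genes$tx_end[i]; len <- e - s
    k <- sample(1:8, 1)
    if (k == 1) return(list(starts = s, ends = e))
    cuts <- sort(sample(seq(s + 100, e - 100, by = 50), 2 * (k - 1)))
    starts <- c(s, cuts[seq(2, length(cuts), by = 2)])
    ends <- c(cuts[seq(1, length(cuts), by = 2)], e)
    list(starts = starts, ends = ends)
  })
  # coding span strictly inside the transcript
  off1 <- round(stats::runif(nrow(genes), 0.05, 0.25) *
                  (genes$tx_end - genes$tx_start))
  off2 <- round(stats::runif(nrow(genes), 0.05, 0.25) *
                  (genes$tx_end - genes$tx_start))
  genes$cds_start <- genes$tx_start + off1
  genes$cds_end <- genes$tx_end - off2
  genes$exon_starts <- vapply(ex, function(x) paste(x$starts, collapse = ","), "")
  genes$exon_ends <- vapply(ex, function(x) paste(x$ends, collapse = ","), "")
  genes <- genes[, c("gene_id", "chrom", "strand", "tx_start", "tx_end",
                     "cds_start", "cds_end", "exon_starts", "exon_ends")]
  rownames(genes) <- NULL
  genes
}

#' Generate two-replica expression tables
#'
#' Expression levels are log-normal; the two replicas differ by a
#' multiplicative log-normal noise with log-scale SD
#' `config$expression$replica_cv`. If `config$expression_dr_shift > 0`,
#' genes whose regulatory domain (basal + extension, see
#' [build_regulatory_domains()]) intersects a susceptible-pool island
#' get that much extra log-scale replica divergence, planting a
#' differential-replica (DR) signal.
#'
#' @param config a [sim_config()] object.
#' @param gene_models output of [generate_gene_models()].
#' @param track output of [generate_cgi_track()] (used to locate the
#'   susceptible pool; may be omitted when `expression_dr_shift = 0`).
#' @return data.frame `gene_id, expr1, expr2` (positive values).
#' @export
generate_expression <- function(config, gene_models, track = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 4L)
  n <- nrow(gene_models)
  base <- stats::rlnorm(n, config$expression$meanlog, config$expression$sdlog)
  cv <- rep(config$expression$replica_cv, n)
  if (config$expression_dr_shift > 0 && !is.null(track) && n > 0) {
    pool <- attr(track, "susceptible_ids")
    if (length(pool) > 0) {
      dom <- build_regulatory_domains(gene_models)
      hit <- associate_regions(track[track$island_id %in% pool, ], dom)
      near <- gene_models$gene_id %in% unique(unlist(hit$region_genes))
      cv[near] <- cv[near] + config$expression_dr_shift
    }
  }
  e1 <- base * exp(stats::rnorm(n, 0, cv / sqrt(2)))
  e2 <- base * exp(stats::rnorm(n, 0, cv / sqrt(2)))
  data.frame(gene_id = gene_models$gene_id, expr1 = e1, expr2 = e2,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic gene-to-term annotation map
#'
#' Random term memberships for testing the enrichment machinery; term
#' sizes are drawn uniformly between `min_size` and `max_size`.
#'
#' @param gene_ids character vector of gene ids.
#' @param n_terms number of terms.
#' @param min_size,max_size term size bounds.
#' @param seed integer seed.
#' @return data.frame `gene_id, term_id`.
#' @export
generate_term_map <- function(gene_ids, n_terms = 20, min_size = 5,
                              max_size = 50, seed = 1L) {
  set.seed(seed)
  max_size <- min(max_size, length(gene_ids))
  rows <- lapply(seq_len(n_terms), function(t) {
    k <- sample(seq(min_size, max_size), 1)
    data.frame(gene_id = sample(gene_ids, k),
               term_id = sprintf("term_%03d", t),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
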