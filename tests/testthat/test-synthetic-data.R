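test_that("generators are deterministic given seed and config", {
  cfg <- small_config(seed = 101)
  t1 <- generate_cgi_track(cfg); t2 <- generate_cgi_track(cfg)
  expect_identical(t1, t2)
  r1 <- generate_replica_reads(t1, cfg)
  r2 <- generate_replica_reads(t2, cfg)
  expect_identical(r1, r2)
  g1 <- generate_gene_models(cfg); g2 <- generate_gene_models(cfg)
  expect_identical(g1, g2)
  expect_identical(generate_expression(cfg, g1, t1),
                   generate_expression(cfg, g2, t2))
})

test_that("track geometry and structural fields are consistent", {
  cfg <- small_config(seed = 5)
  tr <- generate_cgi_track(cfg)
  expect_equal(nrow(tr), cfg$n_cgis)
  expect_true(all(tr$length == tr$end - tr$start))
  expect_true(all(tr$cpg_count >= 1 & tr$cpg_count <= tr$length / 2))
  expect_true(all(tr$gc_fraction >= 0 & tr$gc_fraction <= 1))
  # sorted and non-overlapping within chromosome
  for (chr in unique(tr$chrom)) {
    d <- tr[tr$chrom == chr, ]
    expect_true(all(diff(d$start) > 0))
    expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
  expect_error(sim_config(chromosome_layout = c(chr1 = 10)),
               "sum to n_cgis")
  expect_error(sim_config(n_cgis = 10, chromosome_layout = c(chr1 = 10)),
               "X-designated")
})

test_that("feature bias shifts the susceptible pool's G+C as stated", {
  cfg <- sim_config(n_cgis = 10000, planted_irdm_fraction = 0.5,
                    chromosome_layout = c(chr1 = 9000, chrX = 1000),
                    planting_chrom_bias = c(chrX = 1),
                    feature_bias = list(gc_fraction = -0.02), seed = 3)
  tr <- generate_cgi_track(cfg)
  sus <- tr$island_id %in% attr(tr, "susceptible_ids")
  diff_gc <- mean(tr$gc_fraction[!sus]) - mean(tr$gc_fraction[sus])
  sem <- 0.03 * sqrt(1 / sum(sus) + 1 / sum(!sus))
  expect_lt(abs(diff_gc - 0.02), 3 * sem)
})

test_that("read generation respects conservation and the planted shift", {
  cfg <- small_config(seed = 7)
  tr <- generate_cgi_track(cfg)
  sim <- generate_replica_reads(tr, cfg)
  expect_true(all(sim$calls$methylated_reads <= sim$calls$coverage))
  expect_true(all(sim$calls$methylated_reads >= 0))
  # planted set size per cell line
  n_planted <- round(cfg$planted_irdm_fraction * cfg$n_cgis)
  expect_true(all(lengths(sim$ground_truth$planted) == n_planted))
  # true replica levels differ by exactly the planted shift
  for (cl in names(sim$ground_truth$planted)) {
    tl <- sim$ground_truth$true_levels[[cl]]
    pl <- sim$ground_truth$island_id %in% sim$ground_truth$planted[[cl]]
    expect_equal(unname(abs(tl[pl, 1] - tl[pl, 2])),
                 rep(cfg$planted_shift, sum(pl)))
    expect_equal(unname(tl[!pl, 1]), unname(tl[!pl, 2]))
  }
})

test_that("measured island means track the true levels", {
  # no noise, no planting, very deep coverage: replicas agree closely
  cfg <- sim_config(n_cgis = 100, n_cell_lines = 1,
                    chromosome_layout = c(chr1 = 90, chrX = 10),
                    biological_sd = 0, planted_irdm_fraction = 0.01,
                    planted_shift = 0.5,
                    coverage = list(mean = 1e4, dispersion = 50), seed = 13)
  tr <- generate_cgi_track(cfg)
  sim <- generate_replica_reads(tr, cfg)
  mat <- cgi_mean_methylation(filter_coverage(sim$calls), tr)
  d <- abs(mat$levels[, 1] - mat$levels[, 2])
  planted <- rownames(mat$levels) %in% sim$ground_truth$planted[[1]]
  expect_true(all(d[!planted] < 0.02))
  # planted islands: difference close to the planted shift
  expect_true(all(abs(d[planted] - 0.5) < 0.1))
})

test_that("shallow coverage fails the downstream filter for most CpGs", {
  cfg <- small_config(seed = 9, coverage = list(mean = 5, dispersion = 5))
  tr <- generate_cgi_track(cfg)
  sim <- generate_replica_reads(tr, cfg)
  expect_lt(mean(sim$calls$coverage >= 10), 0.2)
})

test_that("gene models and expression tables satisfy their contracts", {
  cfg <- small_config(seed = 21)
  genes <- generate_gene_models(cfg)
  expect_equal(nrow(genes), cfg$n_genes)
  for (i in seq_len(nrow(genes))) {
    s <- as.integer(strsplit(genes$exon_starts[i], ",")[[1]])
    e <- as.integer(strsplit(genes$exon_ends[i], ",")[[1]])
    expect_true(all(e > s))
    expect_true(s[1] == genes$tx_start[i])
    expect_true(e[length(e)] == genes$tx_end[i])
    if (length(s) > 1) expect_true(all(s[-1] >= e[-length(e)]))
    expect_gt(genes$cds_start[i], genes$tx_start[i] - 1)
    expect_lt(genes$cds_end[i], genes$tx_end[i] + 1)
  }
  # zero genes -> empty annotation, downstream all-intergenic
  g0 <- generate_gene_models(sim_config(n_genes = 0))
  expect_equal(nrow(g0), 0)
  tr <- generate_cgi_track(cfg)
  cls <- classify_gene_region(tr, g0)
  expect_true(all(cls == "intergenic"))
  expr <- generate_expression(cfg, genes, tr)
  expect_true(all(expr$expr1 > 0 & expr$expr2 > 0))
  expect_equal(expr$gene_id, genes$gene_id)
})

test_that("without a planted DR shift, planted-adjacent genes are not set apart", {
  ps <- vapply(1:20, function(s) {
    cfg <- sim_config(n_cgis = 400, n_cell_lines = 2, n_genes = 500,
                      chromosome_layout = c(chr1 = 360, chrX = 40),
                      expression_dr_shift = 0, seed = s)
    tr <- generate_cgi_track(cfg)
    genes <- generate_gene_models(cfg)
    expr <- generate_expression(cfg, genes, tr)
    dom <- build_regulatory_domains(genes)
    pool <- attr(tr, "susceptible_ids")
    hit <- associate_regions(tr[tr$island_id %in% pool, ], dom)
    near <- expr$gene_id %in% unlist(hit$region_genes)
    dr <- compute_dr(expr)
    suppressWarnings(
      ks.test(dr$DR[dr$gene_id %in% expr$gene_id[near]],
              dr$DR[!dr$gene_id %in% expr$gene_id[near]]))$p.value
  }, numeric(1))
  # under the null the KS p-values behave uniformly: not systematically
  # small, and rarely below 0.01
  expect_gt(median(ps), 0.1)
  expect_lte(sum(ps < 0.01), 2)
})

test_that("downstream statistics are invariant to replica labels at shift 0", {
  m <- matrix(runif(40), ncol = 2)
  expect_equal(qdmr_entropy(m)$H_Q, qdmr_entropy(m[, 2:1])$H_Q)
})
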