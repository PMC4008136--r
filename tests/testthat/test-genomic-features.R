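test_that("chromosome bootstrap matches the exact hypergeometric tail", {
  u <- data.frame(island_id = sprintf("i%03d", 1:100),
                  chrom = rep(c("chrA", "chrB"), each = 50))
  # whole universe called: proportions match expectation, p near 1
  res <- chromosome_bootstrap(u$island_id, u, n_boot = 500, seed = 1)
  expect_equal(res$observed_prop, res$expected_prop)
  expect_true(all(res$p_enrich > 0.9))
  # 10 calls all on chrA: exact tail C(50,10)/C(100,10)
  res <- chromosome_bootstrap(u$island_id[1:10], u, n_boot = 1e4, seed = 2)
  exact <- choose(50, 10) / choose(100, 10)
  mc_se <- sqrt(exact * (1 - exact) / 1e4)
  expect_lt(abs(res$p_enrich[res$chrom == "chrA"] - exact),
            3 * mc_se + 1 / 1e4)
  expect_true(res$p_enrich[1] >= 1 / (1e4 + 1))
})

test_that("gene-region classes follow the midpoint rules", {
  # + strand gene, 4 exons, translational start at 11000
  g <- gene_df(tx_start = 10000, tx_end = 30000,
               cds_start = 11000, cds_end = 28000,
               exon_starts = c(10000, 15000, 20000, 26000),
               exon_ends = c(12000, 18000, 22000, 30000))
  isl <- islands_df("chr1",
                    c(8500, 16000, 18500, 100000, 24500, 31000),
                    c(9500, 17000, 19500, 101000, 25500, 32000))
  cls <- classify_gene_region(isl, g)
  expect_equal(as.character(cls),
               c("five_prime",   # 2 kb upstream of translational start
                 "intragenic",   # internal exon
                 "intragenic",   # internal intron
                 "intergenic",   # far from any gene
                 "three_prime",  # final intron
                 "three_prime")) # <3 kb downstream strip
  # - strand gene: mirrored geometry, translational start = cds_end
  gm <- gene_df(strand = "-", tx_start = 10000, tx_end = 30000,
                cds_start = 12000, cds_end = 29000,
                exon_starts = c(10000, 15000, 26000),
                exon_ends = c(12000, 18000, 30000))
  isl2 <- islands_df("chr1", c(30500, 10500, 16000), c(31500, 11500, 17000))
  expect_equal(as.character(classify_gene_region(isl2, gm)),
               c("five_prime", "three_prime", "intragenic"))
  # 5' takes precedence over 3' when genes disagree
  both <- rbind(g, gene_df(gene_id = "gene_0002", tx_start = 5000,
                           tx_end = 9000, cds_start = 5200, cds_end = 8800,
                           exon_starts = 5000, exon_ends = 9000))
  mid <- islands_df("chr1", 8500, 9500)  # 5' of gene 1, 3' strip of gene 2
  expect_equal(as.character(classify_gene_region(mid, both)), "five_prime")
})

test_that("class composition chi-square matches hand evaluation", {
  lv <- c("five_prime", "intragenic", "three_prime", "intergenic")
  all_cls <- factor(rep(lv, each = 25), levels = lv)
  same <- factor(rep(lv, each = 5), levels = lv)
  res <- gene_region_chisq(same, all_cls)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  obs <- factor(rep(lv, c(30, 10, 10, 50)), levels = lv)
  res <- gene_region_chisq(obs, all_cls)
  expect_equal(res$statistic, 44)  # sum((O-E)^2/E) with E = 25 each
  expect_equal(res$p_value, pchisq(44, 3, lower.tail = FALSE))
})

test_that("structural feature tests detect planted differences", {
  set.seed(43)
  mk <- function(gc) data.frame(gc_fraction = gc,
                                length = round(runif(length(gc), 300, 1500)),
                                obs_exp = runif(length(gc), 0.6, 1))
  a <- mk(rnorm(500, 0.68, 0.05))
  b <- mk(rnorm(500, 0.70, 0.05))
  res <- structural_feature_tests(a, b)
  expect_lt(res$p_value[res$feature == "gc_fraction"], 0.001)
  # label swap flips the sign, p unchanged
  res_sw <- structural_feature_tests(b, a)
  expect_equal(res$p_value, res_sw$p_value)
  expect_equal(res$mean_irdm - res$mean_other,
               -(res_sw$mean_irdm - res_sw$mean_other))
  # identical groups -> mean difference 0, p = 1
  res_id <- structural_feature_tests(a, a)
  expect_equal(res_id$mean_irdm, res_id$mean_other)
  expect_true(all(res_id$p_value == 1))
})

test_that("inter-cell-line calls are monotone in the null SD", {
  set.seed(47)
  m <- matrix(pmin(1, pmax(0, rnorm(500 * 5, runif(500), 0.1))), ncol = 5)
  rownames(m) <- sprintf("i%03d", 1:500)
  # a larger null SD tolerates more variation before calling, so its
  # call set nests inside the one from a smaller SD
  strict <- call_icdm(m, sd = 0.03, n_sim = 2e4, seed = 5)
  loose <- call_icdm(m, sd = 0.015, n_sim = 2e4, seed = 5)
  expect_true(all(strict %in% loose))
  expect_gt(length(loose), length(strict))
})

test_that("cross-cell-line enrichment reports signal and degeneracy", {
  set.seed(53)
  u <- sprintf("i%03d", 1:200)
  # islands 1-40 unstable across 5 cell lines, the rest tight
  m <- rbind(matrix(pmin(1, pmax(0, rnorm(40 * 5, 0.5, 0.25))), ncol = 5),
             matrix(pmin(1, pmax(0, rnorm(160 * 5, 0.5, 0.02))), ncol = 5))
  rownames(m) <- u
  icdm <- call_icdm(m, sd = 0.015, n_sim = 2e4, seed = 7)
  res <- icdm_enrichment(list(planted = u[1:40]), icdm, u)
  expect_gt(res$odds_ratio, 1)
  expect_lt(res$p_value, 1e-3)
  # independent random sets: no inflated significance
  ps <- replicate(100, {
    icdm_enrichment(list(all = sample(u, 50)), sample(u, 70), u)$p_value
  })
  expect_lte(mean(ps < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 100))
  # degenerate margin: whole universe in the cross-cell-line set
  res <- icdm_enrichment(list(all = u[1:50]), u, u)
  expect_true(is.na(res$p_value))
})

test_that("Welch group test handles contrasts and degeneracy", {
  # two groups: equals the two-sample Welch t-test
  x <- c(100, 105, 98, 102, 101, 500, 498, 505, 510, 495)
  g <- rep(c("a", "b"), each = 5)
  expect_equal(welch_group_test(x, g),
               t.test(x[g == "a"], x[g == "b"])$p.value)
  expect_lt(welch_group_test(x, g), 0.001)
  expect_error(welch_group_test(x, rep("a", 10)), "2 groups")
  expect_error(welch_group_test(x[1:5], c("a", "a", "b", "b", "c")),
               ">= 2 cell lines")
  expect_warning(p <- welch_group_test(rep(5, 6), rep(c("a", "b"), 3)),
                 "zero variance")
  expect_true(is.na(p))
})
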