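test_that("regulatory domains follow the basal + extension rule", {
  # single + strand gene, TSS at 5e6
  g <- gene_df(tx_start = 5e6, tx_end = 5.05e6, cds_start = 5.001e6,
               cds_end = 5.04e6, exon_starts = 5e6, exon_ends = 5.05e6)
  d <- build_regulatory_domains(g)
  expect_equal(d$basal_start, 5e6 - 5000)
  expect_equal(d$basal_end, 5e6 + 1000)
  expect_equal(d$ext_start, d$basal_start - 1e6)
  expect_equal(d$ext_end, d$basal_end + 1e6)
  # - strand gene: basal is 5 kb upstream of its TSS (the tx_end side)
  gm <- gene_df(strand = "-", tx_start = 5e6, tx_end = 5.05e6,
                cds_start = 5.001e6, cds_end = 5.04e6,
                exon_starts = 5e6, exon_ends = 5.05e6)
  dm <- build_regulatory_domains(gm)
  expect_equal(dm$basal_start, 5.05e6 - 1000)
  expect_equal(dm$basal_end, 5.05e6 + 5000)
  # two genes 10 kb apart: extensions stop at the neighbour's basal edge
  g2 <- rbind(g, gene_df(gene_id = "gene_0002", tx_start = 5.06e6,
                         tx_end = 5.1e6, cds_start = 5.061e6,
                         cds_end = 5.09e6, exon_starts = 5.06e6,
                         exon_ends = 5.1e6))
  d2 <- build_regulatory_domains(g2)
  expect_equal(d2$ext_end[1], d2$basal_start[2])
  expect_equal(d2$ext_start[2], d2$basal_end[1])
  # gene near the chromosome start: extension clipped at 0
  g0 <- gene_df(tx_start = 2000, tx_end = 30000, cds_start = 2500,
                cds_end = 29000, exon_starts = 2000, exon_ends = 30000)
  d0 <- build_regulatory_domains(g0)
  expect_equal(d0$basal_start, 0)
  expect_equal(d0$ext_start, 0)
  # invariants on generated genes
  gen <- generate_gene_models(small_config(seed = 59))
  dg <- build_regulatory_domains(gen)
  expect_true(all(dg$ext_start <= dg$basal_start))
  expect_true(all(dg$ext_end >= dg$basal_end))
  expect_true(all(dg$ext_start >= dg$basal_start - 1e6))
  expect_true(all(dg$ext_end <= dg$basal_end + 1e6))
})

test_that("regions associate with every overlapped extended domain", {
  g2 <- rbind(
    gene_df(tx_start = 5e6, tx_end = 5.05e6, cds_start = 5.001e6,
            cds_end = 5.04e6, exon_starts = 5e6, exon_ends = 5.05e6),
    gene_df(gene_id = "gene_0002", tx_start = 5.06e6, tx_end = 5.1e6,
            cds_start = 5.061e6, cds_end = 5.09e6,
            exon_starts = 5.06e6, exon_ends = 5.1e6))
  d <- build_regulatory_domains(g2)
  regions <- islands_df("chr1",
                        c(5e6 - 2000, 5.054e6, 8e6),
                        c(5e6 - 1500, 5.056e6, 8.0005e6),
                        id = c("in_basal", "spanning", "far"))
  assoc <- associate_regions(regions, d)$region_genes
  expect_equal(assoc$in_basal, "gene_0001")
  expect_setequal(assoc$spanning, c("gene_0001", "gene_0002"))
  expect_length(assoc$far, 0)
  # gene linked to both a called and an uncalled region goes to IRDM-G
  sets <- associate_gene_sets(regions, "spanning", d)
  expect_setequal(sets$irdm_g, c("gene_0001", "gene_0002"))
  expect_length(sets$n_irdm_g, 0)
})

test_that("term enrichment agrees with exact combinatorial oracles", {
  # 20 well-separated genes; term A = genes 1-5; regions hit the basal
  # domains of genes 1-4, 6 and 7 -> 6 associated genes, 4 in the term
  genes <- do.call(rbind, lapply(1:20, function(i)
    gene_df(gene_id = sprintf("gene_%04d", i),
            tx_start = i * 5e6, tx_end = i * 5e6 + 50000,
            cds_start = i * 5e6 + 1000, cds_end = i * 5e6 + 40000,
            exon_starts = i * 5e6, exon_ends = i * 5e6 + 50000)))
  dom <- build_regulatory_domains(genes)
  hit_idx <- c(1:4, 6, 7)
  regions <- islands_df("chr1", hit_idx * 5e6 - 100, hit_idx * 5e6 + 100,
                        id = sprintf("r%02d", seq_along(hit_idx)))
  term_map <- data.frame(gene_id = sprintf("gene_%04d", 1:5),
                         term_id = "term_A")
  res <- term_enrichment(regions, dom, term_map, genes$gene_id)
  expect_equal(res$assoc_in_term, 4)
  expect_equal(res$n_assoc, 6)
  expect_equal(res$p_hyper, oracle_hyper_tail(4, 5, 20, 6),
               tolerance = 1e-12)
  expect_equal(res$p_hyper, 0.01393189, tolerance = 1e-6)
  # binomial component: only the regions at genes 1-4 touch the term's
  # domains; the null hit probability is the covered genome fraction
  expect_equal(res$region_hits, 4)
  term_dom <- dom[dom$gene_id %in% term_map$gene_id, ]
  covered <- sum(term_dom$ext_end - term_dom$ext_start)  # disjoint here
  p_hit <- covered / max(dom$ext_end)
  expect_equal(res$p_binom, pbinom(3, 6, p_hit, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("degenerate term geometries give p = 1", {
  genes <- rbind(
    gene_df(tx_start = 1e6, tx_end = 1.05e6, cds_start = 1.001e6,
            cds_end = 1.04e6, exon_starts = 1e6, exon_ends = 1.05e6),
    gene_df(gene_id = "gene_0002", tx_start = 8e6, tx_end = 8.05e6,
            cds_start = 8.001e6, cds_end = 8.04e6,
            exon_starts = 8e6, exon_ends = 8.05e6))
  dom <- build_regulatory_domains(genes)
  regions <- islands_df("chr1", c(1e6, 8e6), c(1e6 + 200, 8e6 + 200))
  # term covering the whole analysable genome: binomial p = 1
  term_map <- data.frame(gene_id = c("gene_0001", "gene_0002"),
                         term_id = "everything")
  res <- term_enrichment(regions, dom, term_map, genes$gene_id,
                         genome_bp = sum(dom$ext_end - dom$ext_start))
  expect_equal(res$p_binom, 1)
  # no region hits the term: binomial p = 1
  term_b <- data.frame(gene_id = "gene_0002", term_id = "t")
  far <- islands_df("chr1", 1e6, 1e6 + 200)
  res_b <- term_enrichment(far, dom, term_b, genes$gene_id)
  expect_equal(res_b$region_hits, 0)
  expect_equal(res_b$p_binom, 1)
  expect_error(term_enrichment(far, dom, term_b, character(0)), "universe")
})

test_that("replica expression divergence has the stated arithmetic", {
  expr <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                     expr1 = c(2, 3, 0, 0), expr2 = c(2, 1, 5, 0))
  dr <- compute_dr(expr)
  expect_equal(dr$DR, c(0, 0.5, 1))  # equal, |3-1|/4, one replica zero
  expect_equal(attr(dr, "n_excluded"), 1)
  expect_true(all(dr$DR >= 0 & dr$DR <= 1))
})

test_that("median split and Fisher test behave under null and signal", {
  set.seed(67)
  # median split puts ~half the genes on each side
  expr <- data.frame(gene_id = sprintf("g%03d", 1:201),
                     expr1 = rlnorm(201, 3, 1), expr2 = rlnorm(201, 3, 1))
  res <- dr_fisher_test(expr, sprintf("g%03d", 1:60))
  expect_equal(sum(res$table[, "above"]), 100)
  expect_equal(sum(res$table[, "at_or_below"]), 101)
  # same DR distribution in both groups: no inflated significance
  ps <- replicate(150, {
    e <- data.frame(gene_id = sprintf("g%03d", 1:200),
                    expr1 = rlnorm(200, 3, 1), expr2 = rlnorm(200, 3, 1))
    dr_fisher_test(e, sprintf("g%03d", 1:60))$p_value
  })
  expect_lte(mean(ps < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 150))
  # planted divergence in one group is detected
  e <- data.frame(gene_id = sprintf("g%03d", 1:400),
                  expr1 = rlnorm(400, 3, 1))
  e$expr2 <- e$expr1 * exp(rnorm(400, 0, c(rep(1.5, 100), rep(0.05, 300))))
  expect_lt(dr_fisher_test(e, sprintf("g%03d", 1:100))$p_value, 1e-6)
  expect_error(dr_fisher_test(e, character(0)), "non-empty")
})
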