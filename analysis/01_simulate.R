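#!/usr/bin/env Rscript
# Step 1 — simulate the study's inputs.
#
# Generates the synthetic dataset the rest of the workflow consumes: a
# CpG-island track, paired-replica per-CpG RRBS-like read counts for
# five cell lines, gene models, and a two-replica expression table.
# Five percent of islands are planted as truly differential between
# replicas (shift 0.4), drawn mostly from a shared, chrX-biased pool of
# susceptible islands that also carries lower G+C, shorter length and
# lower CpG observed/expected — the structure steps 2-5 try to recover.

library(irdm)

outdir <- "results/data"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 20240101)
track <- generate_cgi_track(cfg)
sim <- generate_replica_reads(track, cfg)
genes <- generate_gene_models(cfg)
expr <- generate_expression(cfg, genes, track)

write_cgi_track(track, file.path(outdir, "cgi_track.bed"))
write_gene_models(genes, file.path(outdir, "genes.bed12"))
write_expression(expr, file.path(outdir, "expression.tsv"))
write_ground_truth(sim$ground_truth, file.path(outdir, "ground_truth.tsv"))
writeLines(attr(track, "susceptible_ids"),
           file.path(outdir, "susceptible_pool.txt"))

for (cl in unique(sim$calls$cell_line)) {
  for (r in 1:2) {
    sel <- sim$calls$cell_line == cl & sim$calls$replica_id == r
    write_methylation(sim$calls[sel, ],
                      file.path(outdir, sprintf("%s_rep%d.meth.tsv", cl, r)))
  }
}

cat(sprintf("Simulated %d CGIs on %d chromosomes, %d cell lines, %d CpG calls.\n",
            nrow(track), length(unique(track$chrom)),
            cfg$n_cell_lines, nrow(sim$calls)))
cat(sprintf("Planted %d differential islands per cell line (pool of %d, %.0f%% on chrX).\n",
            round(cfg$planted_irdm_fraction * cfg$n_cgis),
            length(attr(track, "susceptible_ids")),
            100 * mean(track$chrom[track$island_id %in%
                                     attr(track, "susceptible_ids")] == "chrX")))
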