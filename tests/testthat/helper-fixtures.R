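# Small simulation configs used across test files.

small_config <- function(seed = 11, ...) {
  sim_config(n_cgis = 300, n_cell_lines = 2,
             chromosome_layout = c(chr1 = 140, chr2 = 110, chrX = 50),
             n_genes = 60, seed = seed, ...)
}

# Per-CpG calls for a hand-built island set: `spec` is a list of rows
# (chrom, pos, cov, meth, rep) for one cell line.
calls_df <- function(spec, cell_line = "cellA") {
  do.call(rbind, lapply(spec, function(x)
    data.frame(chrom = x[[1]], pos = as.integer(x[[2]]),
               coverage = as.integer(x[[3]]),
               methylated_reads = as.integer(x[[4]]),
               replica_id = as.integer(x[[5]]), cell_line = cell_line,
               stringsAsFactors = FALSE)))
}

islands_df <- function(chrom, start, end, id = NULL) {
  n <- length(start)
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(end),
             island_id = if (is.null(id)) sprintf("isl_%02d", seq_len(n))
             else id,
             length = as.integer(end - start),
             cpg_count = pmax(1L, as.integer((end - start) %/% 10)),
             gc_fraction = 0.7, obs_exp = 0.8, stringsAsFactors = FALSE)
}

# A single + strand gene with explicit exon structure.
gene_df <- function(gene_id = "gene_0001", chrom = "chr1", strand = "+",
                    tx_start, tx_end, cds_start, cds_end,
                    exon_starts, exon_ends) {
  data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
             tx_start = as.integer(tx_start), tx_end = as.integer(tx_end),
             cds_start = as.integer(cds_start),
             cds_end = as.integer(cds_end),
             exon_starts = paste(exon_starts, collapse = ","),
             exon_ends = paste(exon_ends, collapse = ","),
             stringsAsFactors = FALSE)
}
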