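# irdm — inter-replica differential methylation of CpG islands

`irdm` is an R package plus analysis workflow for a question about
epigenome stability: when the *same* cell line is cultured in two
replicas, which CpG islands (CGIs) nevertheless change their DNA
methylation — and do the *same* islands do so across many cell lines,
marking them as intrinsically unstable? It is aimed at computational
epigenomics users working with RRBS-style per-CpG read counts
(coverage and methylated-read count per CpG, two replicas per cell
line) and a CGI annotation track.

## The method

Per island and sample, methylation is the unweighted mean over
coverage-qualifying CpGs (depth ≥ 10) of `methylated_reads/coverage`.
Two independent callers are intersected:

1. **Entropy caller** (quantitative DMR statistic). With levels
   $m_{r,s}$ over $N$ samples, distances from the one-step Tukey
   biweight mean $T_{br}$ give $m'_{r,s} = |m_{r,s}-T_{br}|$, entropy
   $H_P = -\sum_s p'_{s/r}\log_2 p'_{s/r}$, and the adjusted entropy

   $H_Q = H_P \cdot \left|\log_2\big((\max_s m_{r,s}-\min_s m_{r,s}) + \epsilon\big)\right|$

   A region is differential when $H_Q$ falls below the 5th percentile
   of a simulated null (uniform regions with Gaussian noise of SD
   0.03 for replica pairs; SD 0.015 for multi-cell-line calling).
2. **Read-count caller**: per-island 2×2 Fisher exact test on summed
   methylated/unmethylated reads across the two replicas, with
   Benjamini–Hochberg FDR at 0.05 per cell line.

Islands called by both are IRDM-CGIs. The package then quantifies
recurrence across cell lines (overlap degrees, common / most-common
tiers, a 100-draw Monte Carlo label-permutation null), characterises
the recurrent set (10⁴-sample chromosome bootstrap, four-class
gene-region classification with chi-square, Welch t-tests of G+C /
length / CpG observed-expected ratio, enrichment among islands
differential *across* cell lines), and associates islands with genes
through basal+extension regulatory domains (5 kb up / 1 kb down of the
TSS, ≤ 1 Mb extension) with binomial-over-regions and
hypergeometric-over-genes term enrichment and a median-split Fisher
test of replica expression divergence `DR = |e1−e2|/(e1+e2)`.

A fully seeded synthetic generator produces every input the pipeline
consumes — CGI track, paired-replica reads for several cell lines,
gene models, expression tables — with planted differential structure
(shared, chrX-biased, structurally biased islands), so everything is
testable without downloads.

## Worked example

```r
library(irdm)
res <- run_irdm_pipeline(sim_config(seed = 2024), seed = 99)
rec <- recovery_stats(res$irdm_sets, res$ground_truth)
sapply(res$per_cell, `[[`, "correlation")   # replica agreement
lengths(res$irdm_sets)                      # IRDM islands per cell line
c(rec$sensitivity, rec$fdr)                 # vs planted ground truth
```

On the default conditions (5 cell lines, 2000 islands, 5% planted
with shift 0.4, 80% drawn from a shared chrX-biased pool) the shipped
workflow prints, step by step:

```
Mean replica correlation: 0.977; mean IRDM islands/cell line: 100.8
Recovery of planted islands: sensitivity 1.000, empirical FDR 0.008
Observed shared count 103 vs null max 63; singleton-vs-shared Fisher p = 6e-49
chrX enrichment: observed 0.36 vs expected 0.07, bootstrap p 1e-04
 gc_fraction   0.6709912   0.6969375 1.073612e-10   # common vs other islands, Welch p
885 of 1850 autosomal universe islands are inter-cell-line differential;
90% of replica-differential islands are among them.
Replica expression divergence: merged median 0.069, Fisher p = 0.611
```

Read: replicas agree strongly overall; the planted unstable islands
are recovered essentially completely with under 1% false discoveries;
they recur across cell lines far beyond the permutation null; the
recurrent set is chrX-enriched, has lower G+C, shorter length and a
lower CpG observed/expected ratio; it overlaps strongly with islands
that differ between cell lines; and replica-level expression is
unaffected (no effect was planted).

The numbered drivers under `analysis/` run the same pipeline as a
file-based workflow (simulate → call → overlap → characterise →
gene association), writing tables under `results/`.

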