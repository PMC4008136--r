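---
title: "Detecting inter-replica differentially methylated CpG islands: models and design choices"
author: "irdm package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting inter-replica differentially methylated CpG islands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the data

Cultured cell lines are expected to propagate CpG-island (CGI)
methylation faithfully through mitosis, so two culture replicas of the
same line should agree island by island. `irdm` asks which islands
violate that expectation — which CGIs are *inter-replica
differentially methylated* (IRDM) — and whether the same islands do so
recurrently across many cell lines, which would mark them as
intrinsically unstable rather than randomly perturbed.

The data model is reduced-representation bisulfite sequencing (RRBS)
summarised per CpG: for each cell line, two replicas, and each CpG, a
read coverage and a methylated-read count. Islands come from a
UCSC-style annotation track carrying structural descriptors (length,
CpG count, G+C fraction, CpG observed/expected ratio). All coordinates
are 0-based half-open; methylation is a fraction in $[0,1]$.

## The two-caller model

An island's methylation level in one sample is the **unweighted mean**
over its coverage-qualifying CpGs (depth $\ge 10$) of
`methylated_reads / coverage`. The mean is over CpG fractions rather
than pooled reads: depth weighting is deliberately left to the
read-count test, so the two callers stay sensitive to different
failure modes.

**Entropy caller (QDMR).** For a region $r$ with levels
$m_{r,s}$ across $N$ samples, the Shannon entropy
$H_0 = -\sum_s p_{s/r}\log_2 p_{s/r}$, $p_{s/r} = m_{r,s}/\sum_s m_{r,s}$,
is small when the methylation mass concentrates in few samples. To
make it robust and absolute-level aware, levels are replaced by their
distances from a one-step Tukey biweight mean $T_{br}$,
$m'_{r,s} = |m_{r,s} - T_{br}|$, giving $H_P$, which is then scaled by
the log-range weight

$$ w_r = \left|\log_2\!\frac{\max_s m_{r,s} - \min_s m_{r,s}}{\mathrm{MAX}-\mathrm{MIN}} + \epsilon\right|,
\qquad H_Q = H_P \times w_r , $$

with $\mathrm{MAX}=1$, $\mathrm{MIN}=0$. $H_Q$ vanishes when exactly
one sample carries all the deviation and diverges for exactly uniform
regions. A region is called differential when $H_Q$ falls below a
threshold obtained by simulation: uniformly methylated null regions
with mean $\mu \sim U(0,1)$ and per-sample levels
$\mathrm{clip}(N(\mu,\mathrm{SD}), 0, 1)$, threshold = the 5th
percentile of the null $H_Q$. For two replicas the rule is provably a
cut on the semi-difference $|m_1-m_2|/2$ (the package tests assert the
exact call-set equality), which is what makes the SD parameter
interpretable: SD 0.03 tolerates replica differences up to roughly
$2.8 \times 0.03\sqrt{2}$ before calling.

**Read-count caller (HBA).** Per island and replica, methylated and
unmethylated reads are summed over qualifying CpGs; the resulting
$2 \times 2$ table is tested with a two-sided Fisher exact test
(point-probability rule), and Benjamini–Hochberg FDR is applied across
all tested islands *of one cell line* — each inter-replica comparison
is treated as its own experiment. This caller reflects coverage and
CpG content, which the entropy statistic ignores.

An island is **IRDM** when both callers agree. Downstream, the
**overlap degree** of an island is the number of cell lines calling it;
islands with degree $\ge 2$ form the *common* tier, and the top 5% of
the autosomal common-degree distribution (smallest integer degree whose
tail mass is $\le$ 5%) forms the *most common* tier.

## Null models for recurrence and characterisation

* **Overlap Monte Carlo.** Under the hypothesis that any island is
  equally likely to be called, each of 100 simulations reassigns each
  cell line's call count uniformly without replacement over the global
  intersection universe (islands with data in every cell line). The
  observed singleton vs shared ($\ge 2$) split is compared against the
  simulation-aggregated split by Fisher's exact test; counts are
  *summed* over simulations (not averaged) so the table stays integer
  and stable.
* **Chromosome bootstrap.** $10^4$ draws of the same number of islands
  from the universe; the per-chromosome enrichment p uses the
  $(1+k)/(1+n)$ estimator so it is never exactly zero — a chromosome
  never reached by any draw reports $p \approx 10^{-4}$, not 0.
* **Gene-region classes.** Each island is assigned exactly one of
  5′ / intragenic / 3′ / intergenic from its midpoint: 5′ runs from
  3 kb upstream of the translational start through the first intron;
  intragenic covers internal exons and introns; 3′ the final intron and
  exon; intergenic means $\ge 3$ kb from every gene. The midpoint rule
  (rather than any-overlap) guarantees a single class; across
  disagreeing genes the precedence is 5′ > 3′ > intragenic, favouring
  promoter annotation. The strip $\le 3$ kb downstream of a gene
  matches no in-gene rule and is assigned 3′. Composition is compared
  by Pearson chi-square against the all-island proportions.
* **Inter-cell-line calls (ICDM).** The same entropy machinery applied
  across cell lines (one value per line = mean of its two replicas) on
  the intersection universe, at SD 0.015. Note the direction of the SD
  knob: a larger SD widens the simulated null differences and therefore
  *lowers* the $H_Q$ threshold and calls *fewer* regions; call sets are
  nested accordingly (tested). Tier enrichment among ICDM calls is a
  $2\times2$ Fisher test per tier.
* **Gene association.** Basal regulatory domains (5 kb upstream / 1 kb
  downstream of the TSS, strand-aware) extended up to 1 Mb per side,
  truncated at the neighbouring basal domains and coordinate 0; a
  region associates with every gene whose extended domain it touches.
  Term enrichment requires both the binomial test over regions (null
  hit probability = fraction of the analysable genome covered by the
  term's domains; here the analysable genome defaults to the span
  covered by all domains per chromosome) and the hypergeometric test
  over genes, each BH-corrected at 0.05. Curated regulatory domains
  and real ontology content are outside this package's scope; tests
  use synthetic term maps. Replica expression divergence is
  $DR = |e_1-e_2|/(e_1+e_2)$ per gene; the IRDM-adjacent and remaining
  gene groups are split at the *merged* median and compared by
  Fisher's exact test. A gene associated with both called and
  uncalled islands counts as IRDM-adjacent, keeping the groups
  disjoint.

## The synthetic data generator

The generator replaces the original consortium downloads and defines
the study conditions:

| parameter | default | rationale |
|---|---|---|
| cell lines | 5 | enough for overlap degrees and tiers at desk scale |
| islands | 2000 over chr1–chr5 + chrX | chrX carries 7.5% of islands |
| CpGs per island | Poisson(20), min 4 | typical RRBS-covered CGI |
| coverage | NegBin(mean 30, size 5) | RRBS depth is overdispersed |
| biological noise | SD 0.03 per CpG per replica | matches the calibration SD of the two-replica threshold |
| planted fraction | 0.05 | close to the per-line IRDM rate seen in real 35-line data (~4%) |
| planted shift | 0.4 | clearly separable yet not saturating |
| sharing | 80% of each line's planted set from a common pool | generates the recurrent-island structure |
| pool chrX bias | weight 8 | plants the chromosome enrichment |
| feature bias | G+C −0.02, length ×0.65, obs/exp −0.05 | plants the structural signature |
| cell-line jitter | SD 0.05 (all), +0.2 (pool) | pool islands are unstable across lines too |
| expression DR shift | 0 | no planted transcriptional effect |

Base island methylation is a bimodal Beta mixture (low ≈ 0.05 / high ≈
0.9), mimicking the U-shaped marginal of real CGI methylation. Planted
islands have true replica levels differing by exactly the planted
shift (direction randomised, placed feasibly inside $[0,1]$). Each
CpG's per-replica level is `clip(mu_rep + N(0, sd), 0, 1)`, drawn
independently per CpG; its methylated count is binomial given its
negative-binomial coverage. CpG positions are evenly spaced within
each island, so the same genome underlies every cell line and replica.
Everything is deterministic given the configuration seed.

What the generator does **not** emulate: read-level bisulfite data
(no sequences or alignment artefacts), spatially correlated
methylation along an island, strand asymmetries, copy-number or
coverage biases tied to G+C, and correlated noise between replicas.
Passing tests therefore demonstrate the statistical machinery under a
clean, known-truth model, not performance on real RRBS libraries.
Because per-CpG noise averages down by $1/\sqrt{\text{CpGs}}$ at the
island level while the call threshold is calibrated against
region-level noise of SD 0.03, the default conditions are
conservative: planted islands are recovered with high sensitivity and
few of the unplanted islands are called.

## Numerical choices

* $\epsilon = 10^{-4}$ in the range weight (configurable); the
  regulariser keeps $w_r$ finite when a region's range is 0 or 1.
* One-step biweight constants: centre = median, scale = median absolute
  deviation, $u = (m - \mathrm{med})/(c\cdot\mathrm{MAD} + 10^{-4})$
  with $c = 5$, weight $(1-u^2)^2$ for $|u|<1$ else 0. For $N = 2$
  the weights are equal by symmetry and $T_{br}$ is the plain mean.
* $0\log_2 0 \equiv 0$ throughout; an all-zero profile is treated as
  uniform ($H_0 = \log_2 N$).
* Exactly uniform regions get the $+\infty$ sentinel for $H_Q$ — they
  can never be called, which matters for equal-replica pairs.
* Null thresholds use the empirical type-1 (inverse-ECDF) quantile, so
  a 0th-percentile threshold is the null minimum and calls nothing.
* The most-common cutoff is the smallest integer degree with tail mass
  $\le 5$%; if no degree qualifies (few cell lines, heavy sharing) the
  tier is empty — an all-or-none outcome on tied degrees. At the
  default 5-line configuration the common degrees concentrate at 4–5,
  so the tier is empty; it becomes informative with more cell lines.
* Degenerate inputs: zero-variance feature comparisons warn and report
  p = 1 (equal means) or 0; the Welch group test returns `NA` with a
  warning when every group has zero variance; Fisher tables with an
  empty margin are reported with `NA` rather than an error.

## Problem sizes

The shipped workflow and tests use 2000 islands × 5 cell lines,
$10^5$-region null simulations for thresholds, 100 overlap
Monte Carlo draws, and $10^4$ bootstrap samples — sizes chosen so the
whole analysis is a desk-scale computation while keeping Monte Carlo
standard errors well inside the tolerances the tests assert (for a 5%
calibration at $10^5$ draws, 3 MC-SE ≈ 0.2 percentage points).

## Limitations

The two callers share their input, so the intersection does not double
the evidence; the read-count test mainly prunes entropy calls backed by
few reads. FDR scope is per cell line, not global. The association
step omits curated regulatory domains and term hierarchies. Headline
counts from any real dataset (numbers of islands called, chromosome
percentages, specific gene families) are properties of that dataset
and are only demonstrated qualitatively here through planted structure.

## Running the workflow

```{r workflow}
# from the repository root
# Rscript analysis/01_simulate.R
# Rscript analysis/02_call_irdm.R
# Rscript analysis/03_overlap.R
# Rscript analysis/04_characterize.R
# Rscript analysis/05_gene_association.R
```

Each step prints its findings and writes its tables under `results/`.
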