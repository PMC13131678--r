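---
title: "Methods: percentile-of-local-maxima normalization and NB differential binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: percentile-of-local-maxima normalization and NB differential binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

ChIP-seq and CUT&RUN coverage tracks from the same experiment routinely
differ in global signal magnitude: sequencing depth, immunoprecipitation
efficiency and signal-to-noise ratio all vary between replicates and
conditions. Scaling by total depth alone ignores the signal-to-noise
component, and exogenous spike-in normalization is not always available.
`epinorm` normalizes samples by equalizing a robust summary of the *upper*
signal distribution — the 99th percentile of local-maxima values — and then
carries the normalized tracks through consensus-region construction and
negative binomial differential testing, so that what is tested is exactly
what can be inspected in a genome browser.

# Signal model and the normalization procedure

Per-base coverage is represented run-length encoded (`signal_track`), with
value 0 off any covered run. For each sample of a chromatin target:

1. **Coverage.** Single-end reads contribute their aligned span (optionally
   extended to a fixed fragment length from the 5' end, strand-aware);
   paired-end fragments are counted once, from the leftmost properly paired
   mate over `[start, start + |TLEN|)`. If a matched control (input/IgG) is
   given, it is scaled to the IP's counted-unit total and subtracted per
   base; negative residuals are clamped to 0 by default because all
   downstream statistics assume non-negative coverage. Blacklisted regions
   are zeroed before anything else is computed.
2. **Local maxima.** A local maximum is a maximal constant-value plateau
   whose value strictly exceeds the flanking signal on both sides, with the
   flank defined as 0 beyond the covered ends and across zero-coverage
   gaps. Evaluating the rule at plateau level (rather than per base) is
   what makes "greater than both neighbours" meaningful on integer-valued
   coverage with flat peak tops; it reduces to the per-bin rule when all
   runs are 1 bp. Each plateau contributes one value, unweighted by its
   width — "how high are the peaks", not "how wide".
3. **P99 and scaling.** The per-sample summary is the 99th percentile
   (linear interpolation between closest ranks, quantile type 7) of those
   plateau values: high enough to sit in the enriched tail, below the
   outlier-dominated maximum. The first sample of the target group in the
   sample sheet is the reference, and every sample is multiplied by
   `P99_reference / P99_sample`, after which all P99s are equal by
   construction (the equalization is exact up to floating point, and the
   package tests it at 1e-9 relative tolerance). The conventional printed
   scaling factor `SF = P99_sample / P99_reference` is recorded in the
   report; applying *that* ratio as the multiplier would amplify scale
   differences instead of removing them, so it is only available behind the
   explicit `literal_sf = TRUE` switch.

Per-condition median tracks (per-base median over replicates, mean of the
two central values for even counts) are produced for browsing, and
binned-signal PCA (10 kb bins, `log2(x+1)`, centered, deterministic PC
signs) plus sample correlation matrices quantify how much the scaling
tightened replicate agreement.

## What P99 scaling assumes, and when it bends

The method assumes differential regions are a small fraction of the upper
signal distribution. In a synthetic cohort where 20% of peaks gain 5-fold
in one condition, the top 1% of that condition's maxima *are* the gained
peaks, and the multiplier partially absorbs the biology (we measure this in
the pipeline tests). Likewise, the P99 of all maxima is an extreme-tail
quantile: on a small fixture (1 Mb, 300 peaks) it is carried by the few
highest peaks, and across independently re-sampled cohorts it fluctuates
by 5–10% from count-sampling noise alone. Two practical consequences,
both reflected in the test design:

* the parameter-recovery contract is stated for cohorts whose tracks are a
  shared latent landscape times per-sample amplitude factors (the
  generator's `multiplier_mode = "scale"`), where recovery is exact;
* under plain depth thinning (`multiplier_mode = "depth"`), local-maxima
  values scale like `mu + c*sqrt(mu)` rather than linearly, so a 2x depth
  difference moves P99 by less than 2x at 1 bp resolution. On real
  genomes, with orders of magnitude more maxima and peaks, both effects
  shrink, but they are inherent to percentile-of-extremes normalization
  and worth knowing about.

# Consensus regions

Per-condition peak sets come either from externally called ENCODE
narrowPeak/broadPeak files (column 9 read as -log10 q; the `-1` sentinel
marks peaks excluded from every q-filtered set) or from a deliberately
minimal built-in caller for self-contained use: fixed windows (200 bp
narrow / 500 bp broad), one-sided Poisson upper-tail p-value of the rounded
window sum against `lambda = max(genome-wide mean window signal, scaled
control window mean)`, BH adjustment across all windows, and merging of
significant windows (adjacent for narrow, gaps up to two windows for
broad). It is a stand-in for a full peak caller, not a reimplementation of
one.

The grid then crosses q-value thresholds (default 0.1, 0.05, 0.01, 0.001,
1e-4) with merge distances (default 0, 50, 100, 250, 500 bp): per cell,
filter each condition at q, concatenate, sort, merge regions whose gap is
at most d (`d = 0` merges book-ended regions; a gap of exactly `d`
merges). With the defaults this yields 25 candidate sets plus a summary
table (count, width quantiles, covered bp) from which the user picks the
set matching their signal type. Covered bp is monotone non-increasing in
stringency and non-decreasing in merge distance; region count is
non-increasing in d — the suite asserts all three.

# Differential binding

Normalized signal is summed per region at 1 bp and rounded into a
count-like matrix (sums, not means, so region width keeps its weight).
Rows whose total across samples falls below `min_counts` are dropped.

**Composition scaling.** Four options, all rescaled to geometric mean 1:
`none`; `upperquartile` (per-sample 75th percentile of its non-zero
counts); `rle` (median of ratios to per-region geometric means over
all-positive regions); `tmm` (trimmed mean of M-values against the column
whose upper quartile is closest to the mean, 30%/5% two-sided trims on
M/A, precision weighting). `rle` and `upperquartile` factors absorb depth
and are used directly as effective sizes; `tmm` and `none` factors are
library-size-relative and are multiplied by column sums. The factors carry
this distinction as an attribute so offsets are always coherent —
combining a depth-absorbing factor with a library size again would bias
every log2FC by the depth ratio. In tests, `rle` is cross-checked against
an established median-of-ratios implementation and `tmm` against an
established TMM implementation; neither external package is used in the
computation itself.

**The test.** Per region, a negative binomial log-linear model
`mean = exp(beta0 + beta1 * 1[condition B]) * effective_size` is fitted by
Fisher scoring (the two-group design with fixed offsets makes the
information matrix block-diagonal, so each group is a one-dimensional
Newton solve — vectorized across regions) and `beta1 = 0` is Wald-tested;
`log2FC = beta1 / ln 2` is B over A. Swapping the contrast negates every
log2FC exactly. Groups with an all-zero count vector get a half-count
pseudo-estimate to keep output finite and deterministic.

**Dispersion.** Per region, a method-of-moments estimate (pooled
within-group variance against the overall normalized mean, floored at 0)
is shrunk toward the common (mean) dispersion with weight
`df / (df + prior_df)`, `prior_df = 20`, floored at 1e-6. The weight is
precision-based rather than fixed because at typical replicate counts
(n = 4 vs 4, six residual df) the raw moment estimate has standard
deviation comparable to the dispersion itself; retaining half of that
noise understates Wald standard errors in the low-dispersion tail and, in
our calibration simulations, pushed the observed FDR of a BH-selected set
well above its nominal level (0.12–0.16 at q < 0.05), while the moderated
weight keeps the null type-I rate at p < 0.05 within [0.047, 0.060] across
seeds and the observed FDR under 0.10. `prior_df = 0` recovers the raw
per-region estimator, `prior_df = Inf` the common-dispersion model.

**Classification.** BH-adjusted q-values are thresholded at `alpha` and the
point-estimate log2FC at `±lfc` (post hoc, matching how such cutoffs are
used in practice; at `lfc = 0` an estimate of exactly 0 is unclassifiable
and stays `ns`). Gain and loss sets are exported as sorted BEDs alongside
the full table.

**Offsets off.** With expected near-complete unidirectional loss, any
composition scaling — and even plain library-size offsets — will re-center
the shift away. `offsets = "none"` (CLI `--no-offsets`) disables offsets
entirely; the suite demonstrates the difference on a simulated global
halving, where `rle` re-centers log2FC near 0 and the offset-free run
keeps the median at -1.

# The synthetic-data generator

`sim_config()` defaults describe one 1 Mb chromosome, 300 non-overlapping
peaks (lognormal widths, median 1 kb, sdlog 0.4, placed with a minimum gap
of two fragment lengths so fragment smear cannot fuse adjacent truth
peaks), background 0.02 fragments/bp (about 3x mean coverage at 150 bp
fragments), 10x peak enrichment, NB dispersion 0.05 at the region-count
level (background counts are drawn per 1 kb tile so over-dispersion stays
local), fixed 150 bp fragments emitted as properly paired, coordinate-
sorted SAM records with dummy sequence. Differential truth assigns a
seeded subset of peaks balanced gain/loss folds. Everything is
deterministic given the seed.

What it does *not* emulate: read sequences, mappability, GC bias, summit
shape, chromatin-state autocorrelation, or unbalanced global shifts.
Passing tests on these fixtures therefore demonstrate correctness of the
arithmetic and calibration of the statistics under the stated model — not
robustness to artifacts real data may contain.

# Numerical and design choices

* Coordinates are 0-based half-open everywhere (BED/bedGraph convention);
  chromosome order follows the chrom-sizes file, never the locale.
* bedGraph output uses the shortest decimal representation that
  round-trips to the same double, so write-then-read is the identity and
  outputs are byte-stable; no output file embeds a timestamp, making
  whole-workflow runs byte-reproducible (asserted in the suite).
* Percentile estimator: linear interpolation between closest ranks
  (type 7), recorded in the normalization report.
* The low-count filter uses row totals (not per-sample minima); region
  quantification sums (not averages) per-base signal — both conventions
  are stated in the report headers.
* Problem sizes in the test suite and acceptance script (1 Mb / 300-peak
  normalization cohort, 2000-region calibration matrices, 100-300 kb
  end-to-end cohorts, 200 randomized instances per interval-arithmetic
  oracle) were chosen as the smallest sizes at which the quantities being
  checked are stable, so the whole suite runs in about a minute.

# Known limitations

* Percentile-of-extremes normalization is sensitive to differential signal
  in the extreme tail and to depth-dependent noise scaling (see above).
* The built-in window caller has no fragment-model sharpening and should
  not be compared against dedicated callers beyond its testing role.
* The NB engine supports exactly one two-condition contrast with
  replicates; no covariates, no shrunken-LFC estimator, no TMMwsp variant.
* Control subtraction happens on raw per-base counts with totals-ratio
  scaling before any depth scaling of the IP itself; other orderings are
  defensible but not offered.
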