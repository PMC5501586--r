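---
title: "Methods: modelling ctDNA CNV detectability and classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling ctDNA CNV detectability and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdnascreen)
```

## Overview

`ctdnascreen` asks, entirely in silico, whether copy-number variants (CNVs)
carried by circulating tumor DNA (ctDNA) can support cancer screening from
a blood draw. Plasma cell-free DNA (cfDNA) is mostly normal-cell DNA; the
tumor contributes a small fraction *f* of fragments. A genomic region with
tumor copy number `2 + Δc` therefore changes the expected sequencing depth
over that region by the linear-mixture factor

    E[depth] ∝ 1 + f · Δc / 2,

a percent-scale effect at realistic ctDNA fractions, which makes the
read-count noise model the heart of the problem. The package provides four
connected layers:

1. a **count model** for binned cfDNA read counts (negative binomial after
   outlier masking and GC correction),
2. a **limit-of-detection engine** mapping depth, ctDNA fraction, copy
   change and CNV size to a detection p-value,
3. a **detectability converter** turning tumor segmentation data into
   coarse five-level "ctDNA-detectable" copy profiles on 5 or 100 Mb grids,
4. **classifiers** (nearest-neighbour and random forest) that detect cancer
   and assign tissue of origin from those profiles,

plus synthetic generators for every input, so all claims are testable
against known ground truth.

## The count model

The genome is divided into adjacent 10 kb bins and per-bin read counts `k`
are modelled as negative binomial (NB),

    P(X = k) = (r/(r+m))^r · Γ(r+k) / (k! Γ(r)) · (m/(r+m))^k,

with mean `m` and dispersion (shape) `r`; the variance is `m + m²/r`, so
`r → ∞` recovers the Poisson. On real cfDNA the Poisson underfits badly —
`gof_chisq()` reproduces that comparison on simulated data — which is why
every downstream power number uses the NB.

Before fitting, two preprocessing steps mirror standard read-depth
pipelines:

* **Outlier masking** (`mask_outlier_bins()`). Each bin is one observation
  in sample-dimensional space (its counts across donors); a robust Minimum
  Covariance Determinant (MCD) location/scatter is estimated over bins and
  bins whose Mahalanobis distance from the raw, consistency-corrected
  estimate exceeds 15 are masked. We chose the joint multivariate reading
  (one distance per bin) because a single per-bin distance is what the
  masking rule consumes. The MCD itself is the FAST-MCD C-step algorithm
  with random elemental starts on a working subsample and full-data
  refinement; the default support fraction is 0.75, and the estimator's
  random starts use a fixed internal seed so masking is deterministic and
  idempotent.
* **GC correction** (`gc_correct()`). Per sample, a locally weighted
  regression of count on GC fraction (span 0.3) is fitted over usable bins
  and counts are rescaled multiplicatively to a common target mean, then
  re-rounded to integers so the downstream fit remains a count model. The
  default target is the cohort grand mean, which simultaneously removes
  library-size differences between samples — exactly what the pooled NB fit
  needs; `target = "sample"` instead preserves each sample's own mean for
  workflows that normalise library size elsewhere.

`fit_count_model()` pools usable bins across samples and fits the NB by
maximum likelihood (method-of-moments start). Underdispersed input
(variance below the mean, outside the NB family) caps `r` at 10⁸ with a
flag rather than failing. Goodness of fit uses Pearson's chi-squared over
equal-probability cells (20 by default, duplicate discrete boundaries
merged) with `cells − params − 1` degrees of freedom.

## Limit of detection

A candidate CNV of length `L` spanning whole bins is treated as one
super-bin. Because a sum of `n` i.i.d. NB(m, r) variables with a common
success probability is NB(n·m, n·r), the region model is

    M0 = d · L / ℓ   (expected reads, depth d, read length ℓ),
    R  = r · L / bin_size,

and the affected expectation is `M1 = M0 (1 + f·Δc/2)`. The detection
p-value is the right tail of NB(M0, R) at `⌈M1⌉` for gains and the left
tail at `⌊M1⌋` for losses (losses are our symmetric extension; the original
analysis shows gains). A region is called detectable at p < 0.01.
`min_detectable_size()` scans a 1–250 Mb grid in 1 Mb steps — 1 Mb is the
focal-amplification scale, 250 Mb the largest chromosome — and
`lod_grid()` tabulates the Cartesian product of the axes.

Whether the original analysis aggregated bins or rescaled a single-bin
model to region size is not stated; we adopted the aggregation closure
because it is the unique reading consistent with NB additivity, and we
verify it two ways: the closed-form normal approximation
`z = (f·Δc/2) / sqrt(1/M0 + 1/R)` agrees with the grid search to within
one 1 Mb step whenever `M0 ≥ 10⁴`, and simulated region sums exceed the
detection threshold at the computed tail mass to within ±0.01 over 500
replicates. Note the p-value is a *null* tail mass: the calibration
experiment draws unspiked regions and uses the spiked expectation only to
place the count threshold.

## Detectability profiles

Tumor segmentation records (SEG dialect; log2 segment means converted by
`copies = 2·2^mean`) pass through:

1. **Germline filtering**: records reciprocally overlapping (≥ 50%) a
   population interval with allele frequency > 1% are removed as inherited
   polymorphisms.
2. **Grid averaging**: per 5 Mb or 100 Mb segment, the length-weighted
   average copy deviation `Σ (copies − 2)·overlap / segment_length`;
   uncovered basepairs count as diploid. Overlapping records within a
   sample are resolved with later-record precedence (warned); trailing
   partial chromosome segments are averaged over their true length.
3. **Detectability**: a segment is detectable when `|avg_dev| ≥ 1` — one
   extra copy on average, e.g. a 1 Mb, +5-copy focal event inside a 5 Mb
   segment, or a whole-segment single-copy gain. The threshold is
   inclusive (the worked description of the coarse scenario is "equal to
   or exceed"), and applied symmetrically to deletions.
4. **Discretisation**: symbolic aggregate approximation to cardinality 5.
   The five categories are copy-count semantic (2-copy loss, 1-copy loss,
   neutral, 1-copy gain, ≥2-copy gain), so the breakpoints are midpoints
   between integer copy states (±0.5, ±1.5) rather than Gaussian
   quantiles; Gaussian-quantile SAX would make category membership depend
   on the cohort's deviation distribution, which is not what the category
   names mean. All segments are categorised; the detectable flag is kept
   separate rather than forcing non-detectable segments to NEUTRAL.

## Classification

* **Distance**: per segment 0 / 0.5 / 1 for identical / adjacent / distant
  copy states, summed over segments (`mod_hamming()`); it is a metric on
  the alphabet (checked exhaustively over all 125 per-segment triples).
* **KNN** (`knn_loo()`): each sample classified against all others,
  `k = ⌊√N⌋` of the total sample count (the square-root rule with floor
  rounding; no rounding rule was stated). Ties break by smallest summed
  distance among the tied classes, then lexicographically — deterministic
  by construction.
* **Hierarchical clustering** (`hcluster_profiles()`): average linkage
  (unstated in the source; configurable), typically restricted to the
  random-forest-important segments.
* **Random forest** (`rf_model()`): 100 trees, stratified 10-fold CV,
  copy states encoded as ordered integers −2..2 (they are ordinal; one-hot
  would discard the ordering). The per-split candidate-variable count is
  tuned over `{⌊√p⌋/2, ⌊√p⌋, 2⌊√p⌋}` by CV accuracy; pooled held-out
  predictions and vote probabilities feed the report, and every sample is
  predicted exactly once.
* **Reporting**: per-class TPR/PPV (PPV is `NA` for never-predicted
  classes), one-vs-rest ROC curves with the operating point nearest the
  (0, 1) corner, `important_segments()` (top 50 by Gini importance by
  default, genomic-order tie-breaks; the source states no selection
  threshold), and the misclassification similarity
  `S(A,B) = (α+β)(A_n+B_n)/N` with average-linkage ordering of `max(S)−S`
  for heat-map display.

## The synthetic generators

The generators define the study conditions and carry their own ground
truth:

* **Healthy cfDNA** (`sim_healthy_bins()`): NB counts with mean
  `m · bias(gc) · s_j`, defaults `m = 300` reads per 10 kb bin (≈3×
  haploid coverage at 100 bp reads, the depth regime discussed for
  screening) and `r = 50`. GC fractions are Beta(10, 14.4) (mean ≈ 0.41,
  genomic-like); the bias curve is quadratic in centered GC and normalised
  to unit mean over the drawn GC values so `mean_per_bin` is the marginal
  clean-bin mean whatever the bias amplitude. Outliers: 1% of bins at 10×
  mean, emulating mismapping hotspots. Per-sample scale factors are
  log-normal (sdlog 0.05) to force the preprocessing to normalise
  library size; experiments that probe moment recovery switch this off,
  since it is a nuisance parameter with its own sampling noise.
* **Spike-in** (`spike_cnv()`): re-draws in-region counts with the mean
  scaled by `1 + f·Δc/2` — the same mixture formula the power engine
  assumes, which is precisely what the calibration test is entitled to
  assume and nothing more.
* **Tumor cohorts** (`sim_tumor_cohort()`): per type, Bernoulli recurrent
  events at grid segments (whole-segment records at `2 + Δ` copies) plus
  Poisson passengers; `flatness` scales probabilities to emulate CNV-poor
  types; a signature with no events is the normal class (the source of
  normal profiles was unstated, so flat-profile normals are our
  construction).
* **Germline resource** (`sim_germline_af()`): random intervals with
  uniform allele frequencies over a configurable range.

What the generators deliberately do **not** emulate: fragment-length
biology, sequencing error, within-tumor heterogeneity, subclonal fractions,
correlated passenger structure, and real TCGA recurrence patterns. Passing
the recovery tests therefore shows the machinery is correct and calibrated
under its stated model, not that real cohorts will classify at these
accuracies; the near-perfect separable-cohort numbers are a ceiling by
design, and the published TCGA-scale accuracies (e.g. overall accuracy
near 0.78 at 5 Mb) are not reproducible without that external data.

## Problem sizes and numerical choices

The test suite and acceptance script use: 200,000 bins × 9 donors for
preprocessing recovery (the genome-scale bin count of a 10 kb tiling);
500 replicate regions of 100 bins for power calibration; 1,000 random toy
segmentations against a per-basepair oracle; and a separable cohort of
5 cancer types + normal at 50 samples each on the 5 Mb grid (340 segments
over the 1.7 Gb default pseudo-genome) for classification recovery.
Degenerate inputs fail loudly: singular MCD scatter, constant GC,
underdispersed counts, empty grids and single-class ROC all raise typed
errors rather than returning numbers.

Coordinates are 0-based half-open everywhere in memory; SEG files are
1-based inclusive on disk and converted at the boundary; BED-like
resources are half-open on disk. All stochastic functions accept explicit
seeds and are bit-reproducible under them; `run_pipeline()` derives stage
seeds from one master seed and writes byte-identical artifacts across
reruns.

## Known limitations

* The detectability rule collapses a segment to its average deviation, so
  balanced gains and losses within one segment can cancel; this is
  inherent to the coarse-resolution screening scenario being modelled.
* The region-aggregation closure assumes independent bin counts; long-range
  coverage waves in real cfDNA would inflate the effective dispersion and
  make the printed limits optimistic.
* The KNN square-root rule and the RF tuning grid are heuristics inherited
  from the modelled analysis, not optimised choices.
* `fast_mcd()` is a randomised search; with the fixed internal seed it is
  deterministic, but pathological contamination above the support fraction
  can still defeat it, as with any MCD.
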