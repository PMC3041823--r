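---
title: "Detecting cancer outlier genes with the Gene Tissue Index"
author: "gtindex maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cancer outlier genes with the Gene Tissue Index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtindex)
```

## The problem

Classical differential-expression statistics assume that a disease-related
gene shifts its expression in *all* disease samples. Many oncogenes do not
behave that way: they are strongly over-expressed in a subset of tumours
(an amplified or translocated subtype) and sit at background levels in the
remaining tumours and in normal tissue. A two-sample t-test dilutes such a
signal across the whole disease group; "cancer outlier profile analysis"
statistics were designed for exactly this heterogeneous alternative.

This package implements five per-gene scores for a genes x samples
log-expression matrix split into a normal/reference group (group 1) and a
disease group (group 2):

* the pooled two-sample **t** statistic,
* **COPA** — the r-th percentile (75/90/95, default 90) of the disease
  samples after centring by the all-sample median and scaling by the
  all-sample MAD (x 1.4826, the normal-consistency constant),
* the **Outlier Sum (OS)** — the sum of standardized disease values above
  the boxplot fence `B = q75 + IQR` computed from all samples,
* the **Outlier Robust t (ORT)** — the sum of normal-median-centred
  disease values above the fence of the *normal* samples only, scaled by
  a pooled MAD of group-median-centred values,
* the **Gene Tissue Index (GTI)**, the package's focus.

## The GTI model

The GTI adapts the structure of the Sen poverty index — a headcount ratio
times an income gap — to expression outliers. For gene *j* and group *k*,
with cut-off `B = q75 + IQR` computed from **all** informative samples of
the gene and `A` the set of group-*k* values strictly above `B`:

```
GTI_jk = 100 * (|A| / n_k) * (mean(A) - B) / B      (0 if A is empty)
```

the proportion of outlying samples times their mean *relative* exceedance
above the cut-off, scaled by 100 for readability. The gene's index is

```
GTI_j = GTI_j2 - GTI_j1
```

large and positive when the disease group harbours outliers, negative
when the normal group does. Two design consequences follow:

* Because both factors are proportions/ratios, the GTI is invariant to
  positive rescaling of a gene and — unlike sum-type scores — does not
  grow with the number of samples. This is what makes it usable on
  integrated multi-study matrices where the informative-sample count
  varies per gene (the `multistudy` regime; every statistic here is
  computed per gene over non-missing cells only).
* The relative gap `(mean(A) - B)/B` presumes a positive measurement
  scale, as log-intensity data are. When a gene's cut-off is not positive
  the score is flagged undefined (`NA`) with a diagnostic, rather than
  silently clamped — a wrong sign in `B` would corrupt the ranking.

Degenerate genes are never given infinite scores: a zero MAD (COPA/OS), a
zero pooled centred MAD (ORT) or a zero pooled standard deviation (t)
flags the gene undefined, and undefined genes sort after all defined ones
with `NA` ranks.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `copa_r` | 90 | COPA percentile; 75/90/95 are the accepted values |
| cut-off source | all samples (GTI, OS); normal samples (ORT) | which samples define `q75 + IQR` |
| `n_perm` | 1000 | permutations for empirical p-values |
| `pooling` | per-gene | permutation null: per-gene, or pooled across genes |
| `tail` | upper | one-sided over-expression; `two-sided` uses absolute scores |

All quantiles — `q25`, `q75`, COPA's percentile — use linear interpolation
between order statistics (R's type 7). The convention is not innocuous:
on small informative-sample sets it visibly moves `B`. It is therefore
pinned everywhere and echoed as `quantile_convention=type7` in every
output header.

## Permutation p-values

`permutation_pvalues()` relabels samples uniformly at random (group sizes
preserved) and applies the add-one estimator
`p = (1 + #{null >= observed}) / (1 + n_perm)`, so p-values lie in
`[1/(n_perm + 1), 1]` and are reproducible for a fixed seed. Per-gene
nulls are the default; the pooled mode gains resolution but assumes genes
are exchangeable under the null, which fails when informative-sample
counts differ per gene — the documented caveat for multi-study matrices.

A limitation worth knowing: statistics whose score depends only on the
few samples above a permutation-invariant cut-off (GTI, OS) have strongly
*discrete* permutation distributions on null data — relabelling merely
reallocates a handful of outlying samples — so their permutation p-values
are conservative there. The continuous t statistic calibrates exactly
(its p <= 0.05 rate on pure-null data sits inside the binomial 99% band
around 0.05 in the test suite); GTI p-values on null data land well below
0.05 at the same nominal level. Conservative null behaviour costs power
but never inflates the false-positive rate.

## The simulation benchmark

`simulate_single_study()` generates the stated benchmark world: 1000
genes by 30 + 30 samples of i.i.d. standard normal values, with a
constant `m = 2` added to the first `k` disease samples of one designated
true-positive gene. `roc_experiment()` repeats this 50 times, computes
for each replicate the rank-based p-value of the true positive (the
proportion of genes scoring *strictly* greater, over the total gene
count — ties do not count, and the value can be exactly 0), and turns the
50 p-values per method into a ROC curve over a false-positive-threshold
grid of 0 to 1 in steps of 0.01 (the grid is a knob; the protocol never
stated one), with trapezoidal AUC.

What a green benchmark test does and does not establish: the generator
emulates independent, homoscedastic Gaussian noise with a single additive
spike. Real microarray meta-data have correlated genes, platform effects,
heavier tails and per-gene missingness; the benchmark therefore validates
the *relative* behaviour of the five statistics under the stated world,
not their absolute error rates on real data. The `multistudy` fixture
kind adds per-gene missingness (informative counts uniform on 20..400 by
default) and is used to check the sample-count-bias diagnostic, but it
too inherits the Gaussian null.

Two measured properties of the statistics deserve emphasis because they
are easy to misread as bugs:

* At `k = 10` of 30 disease samples (one-sixth of all samples spiked),
  all five methods are comparably good — AUCs within 0.08 of each other
  in the test suite, GTI at about 0.87.
* When **all** disease samples are spiked (`k = n2`), the all-sample
  fence `q75 + IQR` climbs into the shifted disease cluster: with a huge
  spike (`m = 10`) no disease value exceeds it and GTI and OS score the
  true positive exactly 0, while COPA's all-sample median/MAD absorb the
  shift similarly. Only ORT and t, which estimate location/spread from
  (or centre by) the groups separately, retain power. Group-wide shifts
  are the biomarker profile, not the outlier profile; the subset-outlier
  statistics are not designed for them. The corresponding acceptance
  test asserts the original all-methods claim and is deliberately left
  failing, with the measured rates, rather than weakened.

## Method-comparison diagnostics

`top_n_overlap()` decomposes the union of the per-method top-100 lists
into the full Venn lattice (counts plus explicit gene lists, so claims
like "N genes unique to one method" are mechanically recomputable), and
`score_vs_samplecount_correlation()` computes the Spearman correlation
(average ranks for ties; scores are converted to ranks) between each
method's scores and per-gene informative-sample counts. On a 2000-gene
null multistudy matrix the suite checks the directional finding:
|rho| < 0.1 for GTI and t, while OS — a sum over outlier samples, hence
growing with sample count — correlates strongly (about 0.6 in the test
configuration).

## Numerical and design choices

* Quantile type 7 everywhere; recorded in output metadata.
* Strict cut-off semantics: a value exactly equal to `B` is never an
  outlier (for OS, ORT and GTI).
* Rank ties broken by gene identifier, lexicographically, so score tables
  are byte-reproducible; Spearman uses average ranks.
* Score-table, permutation and ROC outputs carry `#`-prefixed headers
  with version, seed and configuration.
* The bespoke simulation p-value divides the strict-greater count by the
  total gene count, exactly as the protocol prints it; the conventional
  `(r + 1)/(n + 1)` estimator is available as `variant = "add-one"` but
  is never used in the reproduction.
* All randomness flows from explicit integer seeds; replicate seeds in
  `roc_experiment()` are drawn once from the master seed, so the full ROC
  table reproduces exactly.

## Known limitations

* No normalization: input is assumed pre-normalized, log-scale, one row
  per gene. Values above 50 trigger a raw-intensity warning on read.
* No parametric p-values; only permutation nulls are offered.
* GTI/OS permutation p-values are conservative on small null datasets
  (discreteness, above).
* The headline multi-study results of the motivating analysis depend on
  a large proprietary compendium and are reproduced here only at the
  level of directional, synthetic-data properties.
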