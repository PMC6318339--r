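---
title: "Methods: region-resolved mucosa proteome analysis"
author: "mucosaAtlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region-resolved mucosa proteome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mucosaAtlas)
```

This vignette documents the statistical procedures implemented by
`mucosaAtlas`, the assumptions behind them, the defaults and why they were
chosen, what the synthetic cohort generator does and does not emulate, and
the numerical conventions the package commits to.

# Data model

The central container is `ProteomeMatrix`, a `SummarizedExperiment` holding
one nonnegative `abundance` assay (proteins × samples) and a scale tag:

* `ibaq` — intensity-based absolute quantification, the input scale;
* `fot` — fraction of total: each iBAQ value divided by the summed iBAQ of
  all proteins in the same sample, so unfiltered columns sum to 1;
* `ifot` — FOT × 1e5, a readability rescaling for low-abundance proteins.

Zero is the only missingness code: label-free proteomics does not
distinguish "absent" from "below detection", and a 0 ⇔ not-detected
convention keeps FOT denominators and detection statistics well defined.

Sample metadata carries the anatomical region (Ca, Fu, LC, GC, AI, An, Py),
the tissue class (N = normal, TNT = tumor-nearby tissue, T = tumor) and the
derived stomach *section*: proximal = {Ca, Fu, LC, GC}, distal =
{AI, An, Py} — a pure function of region, exposed as `regionSection()`.

# Preprocessing

**Normalization order.** FOT is computed on the *full* identification
matrix, before any filtering, because the fraction-of-total denominator is
defined over all proteins identified in a sample.  Filtered matrices
therefore have column sums slightly below 1e5; this is intentional and
preserved.  Whether normalization should precede or follow filtering is
genuinely open for this kind of data; computing it first keeps FOT values
of retained proteins independent of the filtering parameters.

**High-confidence filters.**  A (protein, sample) detection is kept iff it
has ≥ 1 unique peptide and ≥ 2 strict peptides (peptides with a
search-engine ion score above 20, counted upstream of this package); a
protein enters the global high-confidence set iff ≥ 2 samples of a single
region detect it.  "Two cases" means two distinct samples; in the reference
design each person contributes at most one sample per region, so samples
and subjects coincide there, but `distinct_subjects = TRUE` is available
for designs where they do not.  Both thresholds are arguments.  Filtering
is monotone: adding evidence can only grow the kept set (a property the
test suite checks).

# Atlas statistics

All detection statistics use only `abundance > 0`, which makes them
invariant to monotone rescaling (iBAQ vs FOT vs iFOT).

* **Core proteome**: detection frequency > 0 in every one of the seven
  regions (threshold configurable).
* **Region-specific proteins**: detection frequency ≥ 75% in 1–2 regions
  and ≤ 25% elsewhere.  The boundaries are inclusive, as printed.  The
  default *strict* reading requires *every* non-enriched region to be
  rare; a *loose* reading (≥ 3 rare regions) is available because the
  phrase "rarely seen in 3 or more regions" admits both.  Frequencies
  falling between 25% and 75% outside an enriched pattern yield "other".
  The per-region frequency reading (rather than frequency among all
  samples pooled) is used because region-balanced sampling makes the
  per-region fraction the quantity that "seen ≥ 75% of times in a region"
  most plausibly denotes.
* **Section structure**: each region is represented by the mean per-sample
  FOT of every protein; the 7 × 7 Spearman correlation matrix is clustered
  (average linkage on 1 − correlation) and cut at two clusters.
* **Section markers**: Student's equal-variance *t*-test (Welch optional)
  on log2(iFOT + 0.01), flagged at |log2 fold change| ≥ 2 and p < 0.05,
  fold change computed on arithmetic mean iFOT with the same pseudocount.
  The pseudocount 0.01 is of the order of the smallest nonzero iFOT values
  in practice; it bounds log ratios for proteins absent from one section.
  Raw p-values are the default (matching common practice for this marker
  definition); a Benjamini–Hochberg switch is exposed.  Proteins with zero
  variance in both groups have no defined test and are excluded with a
  warning.
* **Co-expression modules**: proteins with median iFOT > 1 in ≥ 1 region,
  represented by their 7-value region-median profiles, clustered by
  average-linkage on 1 − Pearson correlation and cut at 5 modules.  The
  module-detection algorithm is this package's own choice — the analysis
  it mirrors names none — so the distance, linkage and cut are all
  arguments, and module labels should be treated as exploratory.
* **CV%**: 100 · sd/mean per protein over detected values (sample sd,
  ≥ 2 detections required, else undefined).

# Reference intervals and outlier calling

For each protein the 10th and 90th percentiles of its abundance across the
normal cohort give the upper limit `P90 + 3 × (P90 − P10)`; a query value
strictly greater than the limit is an outlier call.  Conventions:

* **Percentile estimator**: linear interpolation between order statistics
  (type 7, the `quantile()` default) — reproducible and ubiquitous; the
  formula's source does not name an estimator.
* **Zeros included** by default.  Including not-detected values makes the
  RI of a normally-absent protein collapse toward zero, so any solid
  detection in a tumor becomes an outlier — the biologically interesting
  case.  `detected_only = TRUE` switches to percentiles over detected
  values.
* **min_ref = 10**: below ten reference values the percentiles are too
  unstable; such proteins are kept in the table with `defined = FALSE` and
  never called.
* **Strict inequality**: a value exactly at the limit is not an outlier
  ("higher than the upper limit").
* **Pan-stomach RI** by default: all normal samples pooled, regardless of
  region — per-section RIs can be built by subsetting the metadata.

Outlier calling is monotone in every coordinate (raising a value can only
add calls), and `subsampleStability()` quantifies how per-protein medians
move under resampling a fraction of the cohort (default 10–80%, 100
repetitions, with replacement), reporting the median of medians and the
across-repetition IQR; the exact summary statistic is this package's
choice of a stability read-out.

# Subtyping by consensus clustering

Features are outlier proteins detected in ≥ ceil(20% × n) patients and
called outliers in ≥ 75% of the *detecting* patients.  The denominator
choice (detecting patients vs the whole cohort) is ambiguous in the
definition this implements; detecting patients is the default and a switch
is exposed.  Features enter as continuous log2(iFOT + 0.01) patient
profiles (a `binary_features`-style analysis can be run by passing the call
matrix instead); undetected values stay as transformed zeros, no
imputation.

Consensus clustering re-implements the published parameterization:
per iteration, 90% of patients are subsampled *without replacement*
(the convention of the reference implementation of this method),
clustered by average-linkage hierarchical clustering of 1 − Pearson
correlation, and cut at each k in 2..10; the consensus entry of a patient
pair is its co-clustering count over its co-sampling count.  Final labels
come from average-linkage clustering of 1 − consensus.  500 iterations is
the published default; tests use 100 for speed.  All randomness flows from
one integer seed, and results are invariant to patient input order up to
label permutation.

**Choosing k.**  The default rule is a stability-gated delta-area
criterion.  Write A(k) = 1 − mean off-diagonal consensus (the area under
the consensus CDF) and Δ(k) its relative change.  A plain argmax of Δ is
fooled on structureless data: average linkage tends to split off
singletons at small k, which deflates A(k_min) and inflates the relative
change just above it, so pure noise would get k = 3.  The implemented rule
therefore only lets k values with stable consensus compete — PAC =
F(0.9) − F(0.1) at most 0.1 — and returns the minimum k when no k is
stable (structureless data), the behavior one wants from a null input.
Ties go to the smaller k.  PAC minimization is available as
`method = "pac"`, and a forced k is accepted throughout the reporting
functions for analyses that fix the subtype count a priori.

# The synthetic cohort generator

`cohortConfig()` + `simulateReferenceCohort()` / `simulateTumorCohort()` /
`simulateNormalQuery()` generate cohorts with planted, recoverable
structure.  Defaults emulate the reference study conditions: 82 normal
samples (Ca 12, Fu 12, LC 11, GC 12, AI 15, An 10, Py 10; one sample per
region per subject), 58 paired T/TNT patients, and 2500 proteins whose
base log10 abundances are uniform over 7 decades.

* **Noise**: per-entry lognormal with σ_log10 = 0.35.  For a lognormal,
  CV = sqrt(exp((σ_log10 ln 10)²) − 1) ≈ 96%, which puts the simulated
  per-protein CV% in the regime reported for biopsy cohorts of this kind
  (close to 95%).
* **Detection**: Bernoulli with probability logistic in the true log10
  abundance (slope 8 per decade, midpoint 1.5).  The reference analysis
  reports no missingness mechanism; the logistic model is this package's
  stated assumption, with the steep slope reflecting the relatively sharp
  intensity floor of data-dependent acquisition.  About 40% of simulated
  proteins sit essentially below the floor, so the high-confidence
  universe is ~1600–1700 proteins.
* **Region-specific proteins** (70): detection probability 0.95 in their
  1–2 enriched regions (pairs drawn within a section, the Py/An-style
  pattern) and 0.05 elsewhere.
* **Section effect**: 140 marker proteins (≈ 5.6% of the proteome,
  matching the observed proportion of fourfold markers in this tissue)
  shifted by `section_effect_log2` = 2 (fourfold) in their home section,
  *plus* a graded section program: every non-planted protein receives a
  proximal-vs-distal shift drawn from N(0, 0.75 log2), half in each
  direction.  Real sections differ through broad, mostly sub-fourfold
  expression programs (gland composition gradients), and without this
  component a rank-correlation analysis of the simulated regions would be
  dominated by detection noise rather than biology.
* **Tumor subtypes**: 3 subtypes × 40 signature proteins.  Signature
  candidates are planted as proteins sitting just above the detection
  floor — baseline detection probability drawn uniformly (in logit) from
  [0.10, 0.25] — so they survive the two-cases-per-region filter yet have
  near-zero reference percentiles.  Each tumor boosts its own subtype's
  signature by `outlier_boost_log2` = 4 (16-fold); the paired TNT sample
  expresses the same boost scaled by `tnt_attenuation` = 0.5, modeling
  TNT as attenuated tumor signal.  By construction expected per-sample
  outlier counts order T > TNT > held-out N.
* **Evidence**: each detected entry receives filter-passing peptide counts
  with probability 0.95, otherwise a sub-threshold pattern (no unique
  peptide, or fewer than two strict peptides).
* **Determinism**: R's Mersenne-Twister under a single config seed;
  identical seeds give bit-identical cohorts.  Derived stage seeds (hashed
  from stage names) let the pipeline rerun stages independently.

**What the generator does not emulate**: correlated detection across
peptides or samples, batch and acquisition-order effects, interference
and ratio compression, subject-level covariance between a person's
regions, compositional coupling beyond the FOT constraint, survival-time
dependence on subtype, and intra-tumor heterogeneity.  Passing the planted
recovery tests therefore demonstrates the correctness and calibration of
the *methods* under a clean generative model, not performance on real
cohorts.

# Numerical conventions and degenerate inputs

* TSV interchange, UTF-8, "." decimal, no quoting; first matrix column
  header is `protein`.  Reals are written with 17 significant digits so
  write→read round-trips are exact for doubles; integer and boolean fields
  round-trip bit-exactly.
* iFOT column sums are checked to 1e-9 relative; FOT to 1e-12.
* All-zero samples abort normalization with the sample named.  Constant
  region vectors abort the correlation analysis.  All-constant feature
  matrices abort consensus clustering.  Consensus pairs never co-sampled
  (impossible at the default 90%/100-rep settings) fall back to 0.
* Ties in `chooseK` go to the smaller k; `cutree` label numbering is
  arbitrary, so cluster identities are only meaningful up to permutation
  (tests compare via the adjusted Rand index).

# Problem sizes

The shipped tests and the acceptance script run the full default cohort
(2500 proteins × 82 + 58 + 58 + 21 samples) for the specificity,
sensitivity and subtype-recovery checks, 20 seeds for the section-recovery
rate, 100 consensus iterations for subtyping, and down-scaled cohorts
(400–500 proteins, 4–6 samples per region) for the orchestration and
round-trip tests.  These sizes were chosen so the whole suite completes in
a few minutes on a single core while keeping every Monte-Carlo margin far
from its threshold.

# Known limitations

* The co-expression module step is a stand-in for an unspecified method;
  module boundaries depend on the distance and cut chosen.
* The RI assumes exchangeable reference samples; it does not model
  subject effects (a subject contributing several regions appears several
  times).
* Outlier calling is one-sided (overexpression only), as defined.
* `chooseK` is a heuristic; for borderline structure inspect the consensus
  CDFs and PAC values rather than trusting a single number.
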