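---
title: "Methods: deriving and applying the ClinicoMolecular Triad Classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deriving and applying the ClinicoMolecular Triad Classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmtc)
```

## The problem and the model

Oncologists stratify breast cancer into three pragmatic risk groups: low-grade
ER-positive disease that responds to endocrine therapy (ET); high-grade
ER-positive disease with a poor prognosis despite ET; and the
Her2-positive/triple-negative (Her2+/TN) spectrum, which carries a poor
prognosis but the highest rate of pathological complete response (pCR) to
neoadjuvant chemotherapy. The ClinicoMolecular Triad Classification (CMTC)
is an expression-based counterpart of that stratification: a gene signature is
derived by contrasting Her2+/TN tumors against the rest, the cohort is cut
into three clusters on that signature, and new samples -- possibly measured on
a different array platform -- are assigned to the cluster whose mean
expression profile (centroid) they correlate with best.

Formally, after preprocessing, each sample is a vector of log2 ratios
$x_{ij} = \log_2(v_{ij} / \bar v_{i\cdot})$, the log2 of each gene's intensity
over its mean intensity across all samples on the same platform. The
classifier is the triple of centroids $c^{(1)}, c^{(2)}, c^{(3)}$ (per-group
mean log2-ratio profiles over the signature genes). A sample $x$ is assigned
to $\arg\max_g \, r(x, c^{(g)})$, with $r$ the Pearson correlation over the
genes shared between the model and the target platform. The correlation to
the high-risk centroid, $r_3$, is additionally reported as a continuous
"r-index" -- the similarity of a tumor's expression pattern to the
Her2+/TN-enriched group, used as a predictor of pCR.

## Preprocessing

`preprocess_pipeline()` runs four deterministic steps:

1. **Quantile normalization** (`quantile_normalize`): every sample column is
   forced onto the common reference distribution (mean of the column-sorted
   values by default; median optional). Tied values within a column receive
   the mean of the reference values their ranks span, which makes the
   transform deterministic and order-independent.
2. **Intensity flooring** (`floor_intensities`): intensities below 16 are
   raised to 16, the MAQC-style floor that keeps near-background values from
   producing extreme log ratios. Flooring is idempotent and applied after
   normalization; the reverse order is also supported.
3. **Probe collapsing** (`collapse_probes_to_genes`): one row per gene
   symbol, keeping the probe with the highest mean intensity (`max_mean`,
   default) or taking per-sample medians. Collapsing runs before the ratio
   step so "highest mean intensity" refers to actual intensities; this
   ordering is the package's choice -- the normalization-then-floor-then-ratio
   order of the remaining steps is fixed.
4. **Log2 ratio to the per-probe mean** (`log2_ratio_to_mean`): the
   *arithmetic* mean is used, as is conventional for "ratio to average
   signal". Note that the mean of log ratios about an arithmetic mean is
   slightly negative (Jensen's inequality); rows are *not* re-centered to
   zero, because the downstream correlations are location-invariant anyway.

Background subtraction is treated as already applied by the scanner software
and is not reimplemented.

## Signature derivation

`derive_cmtc()` implements the two-screen derivation:

* **Screen 1** (`screen_differential_probes`): per-probe two-sample t-test of
  Her2+/TN vs the rest, keeping probes with Bonferroni-corrected $p < 0.01$
  (factor = number of probes tested). The default statistic is **Welch's t**,
  not the pooled-variance t. This is deliberate: the "rest" class is a
  mixture of the low-risk and intermediate groups and is both larger and more
  variable than the Her2+/TN class on exactly the probes where the
  intermediate group tracks the high-risk direction. The pooled statistic is
  miscalibrated there and discards the only probes able to separate the two
  non-Her2+/TN groups, after which no three-cluster structure is recoverable.
  Welch's statistic handles the unequal variances correctly; the pooled
  variant remains available via `derivation_config(ttest_variant = "pooled")`.
* **Clustering** (`hierarchical_three_cluster`): agglomerative clustering of
  samples with distance $1 - r$ (Pearson) and average linkage -- the
  era-standard choice for expression heat maps -- cut to the three *main*
  clusters. Average linkage happily isolates lone outliers at $k = 3$, so
  when the plain cut yields a cluster below 2 samples the tree is cut
  progressively deeper until three clusters of at least that size exist, and
  remaining samples join the main cluster at the smallest average distance.
  This is the dendrogram-reading a human performs when told to mark the
  "three main clusters", made explicit and deterministic.
* **Screen 2** (`screen_anova_probes`): one-way fixed-effects ANOVA across
  the three interim clusters, restricted to the screen-1 probes, keeping
  probes with uncorrected $p < 0.001$. The threshold is uncorrected by
  design; the corrected criterion belongs to the final verification step.
* **Overlap exclusion** (`exclude_overlapping_genes`): probes whose gene
  symbol appears in any of a catalog of published prognostic signatures are
  removed, at the *gene* level, so the final signature's prognostic content
  is not inherited from existing signatures.
* **Identity assignment** (`assign_group_identities`): after re-clustering on
  the final probe set, CMTC-3 is the cluster with the highest Her2+/TN
  fraction; of the remaining two, CMTC-1 has the lower mean grade (ties break
  toward the higher ER+ fraction; a full tie is an error demanding manual
  assignment rather than a silent guess).
* **Verification** (`verify_group_separation`): at least 90% of the final
  probes must reject the three-group ANOVA at $p < 10^{-5}$, and *every pair*
  of groups must be separated by at least 5% of the probes at
  Bonferroni-corrected $p < 0.01$. A phenotype-anchored signature cannot
  separate every pair on every probe -- roughly half its probes are expected
  to be identical in the two non-anchor groups by construction -- so the
  pairwise criterion asks for clear separating probes for each pair, not a
  per-probe universal. Both fractions and both thresholds are arguments.

All derivation steps are deterministic: there is no random initialization
anywhere in the pipeline.

## Classification across platforms

`classify_cohort()` intersects the model's gene symbols with the target's
(refusing below 50% shared genes by default), optionally gene-wise
median-centers the target cohort, and correlates each sample with the three
centroids. Pearson correlation on log2 ratios is invariant to affine
transforms $v \mapsto a v + b$ ($a > 0$) of a profile, which is precisely the
property that lets the classifier transfer across platforms with different
gains and offsets; the median-centering removes residual per-gene baseline
shifts between platforms. Exact correlation ties and zero-variance profiles
return `"unclassified"` rather than an arbitrary call.

## Outcome evaluation

The evaluation battery uses the standard machinery: chi-square tests of
independence without continuity correction (Fisher's exact test for sparse
2x2 tables), Kaplan-Meier product-limit curves with the log-rank test and Cox
proportional-hazards fits (Efron ties) via the survival package, and ROC
analysis in which the AUC is computed exactly as the normalized Mann-Whitney
U statistic with midranks -- so a binary predictor's AUC is identically
(sensitivity + specificity)/2. AUC confidence intervals use a stratified
bootstrap (resampling positives and negatives separately, 2,000 replicates by
default, seeded) so binary and continuous predictors go through the same
machinery. Percentages in rate tables are rendered to one decimal with
half-up rounding, the clinical-table convention.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the method assumes,
not any particular data set:

* **Intensity model**: per-probe baseline log2 levels are N(8, 1.5)
  (log-normal intensities), with per-sample N(0, `noise_sd`) noise on the
  log2 scale. This mimics bead-array intensity distributions and leaves the
  floor-16 rule occasionally active (about 1.3% of baseline draws fall below
  log2(16) = 4).
* **Planted groups**: `n_informative_probes` carry a shift of
  `effect_size` (default 1.5 log2 units) with a random sign per probe --
  negative in group 1, positive in group 3, making the two patterns exactly
  opposed. Group 2 is intermediate but distinct: half of the informative
  probes follow the group-3 direction and half the group-1 direction, rather
  than averaging, so the intermediate group has its own recognizable pattern.
* **Phenotype coupling**: the Her2+/TN flag is drawn per group
  (defaults 6.7%/7.7%/92.3%) and then *realized through the receptor fields*
  (a Her2+/TN sample is either Her2+ or ER-/PR-/Her2-; a non-Her2+/TN sample
  always carries at least one hormone receptor), so the flag is always
  consistent with ER/PR/Her2.
* **Covariate margins**: age, size, nodal, grade and ER margins default to
  the published cohort proportions; they are drawn independently per group
  (the source tables publish margins, not joint distributions, and no joint
  structure is claimed).
* **Outcomes**: exponential relapse times with per-group hazards (defaults
  0.010/0.030/0.028 per month -- together with exponential censoring at rate
  0.044 these reproduce the published long-term relapse fractions of roughly
  19%/40%/39%), an ET hazard multiplier applied only to ET-treated ER+
  samples (default 0.5/1/1: benefit confined to group 1), and Bernoulli pCR
  (defaults 6%/8%/42%) observed only for neoadjuvant-treated samples.
  Outcome draws use their own seed (config seed + 1) so they do not reuse the
  RNG positions consumed by expression noise.
* **Second platforms** (`generate_validation_platform`): a random gene subset
  is retained, probe IDs are renamed, and intensities are transformed
  $v' = \text{gain} \cdot v + \text{offset} + \varepsilon$, clipped below at
  a small positive constant.

What the generator does **not** emulate: gene-gene correlation networks,
batch effects beyond the affine platform transform, non-proportional
hazards, competing risks, or informative censoring. Passing recovery tests on
these cohorts therefore demonstrates that the pipeline's logic is correct
under its own assumptions -- not that the classification is valid on real
tumors, which is a clinical-validation question.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, chosen so the
statistical properties under test are comfortably identifiable: derivation
recovery uses 150 samples x 2,000 probes with 200 informative probes at
effect 1.5 and noise 0.5; calibration checks use 5,000-15,000 samples per
group for binomial margins; Cox recovery uses 200 replicates of n = 2,000;
the ET-benefit scenario uses 300 samples per group with a low censoring rate
(0.005/month) so each arm accrues enough events for the log-rank comparison;
pCR AUC is averaged over 20 replicate cohorts of 80/80/88 (the published
neoadjuvant cohort's size) because a single cohort of 248 estimates an AUC
with sd near 0.035. Tolerances: oracle comparisons (product-limit, log-rank
O-E, Mann-Whitney AUC, chi-square) are exact to 1e-10 or better; recovery
comparisons use the bands stated with each test.

## Known limitations

* The derivation assumes the Her2+/TN anchor is informative; if the
  phenotype is uncorrelated with expression structure, screen 1 is empty and
  the pipeline stops with an error rather than inventing a signature.
* The three-main-clusters rule guarantees three non-degenerate clusters but
  cannot conjure a third group out of a cohort that genuinely has two; in
  that case the resulting triad is a partition of convenience and
  `verify_group_separation()` flags the failure.
* `cox_model()` fits the terms jointly; per-term univariate tables are the
  caller's loop.
* The ET-benefit analysis is observational by design (arms are simulated as
  assigned, not randomized), mirroring the confounding structure it is meant
  to demonstrate.
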