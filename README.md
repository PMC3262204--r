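# cmtc

Derivation, application and clinical evaluation of the **ClinicoMolecular
Triad Classification (CMTC)** — a three-group breast cancer classification
built from bulk expression profiles and anchored on the
Her2-positive/triple-negative (Her2+/TN) phenotype.

Oncologists stratify breast cancer into three pragmatic risk groups:
low-grade ER+ disease (responds to endocrine therapy), high-grade ER+
disease (poor prognosis despite endocrine therapy), and the Her2+/TN
spectrum (poor prognosis, highest pathological-complete-response rate under
neoadjuvant chemotherapy). CMTC is the expression-based counterpart: a
signature derived by a two-screen procedure (Bonferroni-corrected t-test of
Her2+/TN vs rest at corrected *p* < 0.01; three-way hierarchical clustering;
per-probe ANOVA across the clusters at *p* < 0.001; exclusion of genes
overlapping published prognostic signatures), followed by a
correlation-to-centroid classifier. A sample *x* over the signature genes is
assigned to

    argmax_g  r(x, c_g),   g in {CMTC-1, CMTC-2, CMTC-3}

where *c_g* is the per-group mean log2-ratio centroid and *r* is the Pearson
correlation over the genes shared with the target platform — a statistic
invariant to affine intensity distortions, which is what lets the classifier
transfer across array platforms. The correlation to the CMTC-3 centroid
(`r_index`) doubles as a continuous predictor of pathological complete
response.

The package contains, as first-class tested code, a seeded synthetic-cohort
generator that reproduces the statistical structure the method assumes
(opposed group-1/group-3 patterns with a distinct intermediate group,
phenotype coupling, group-dependent relapse hazards, endocrine-therapy
benefit confined to group 1, pCR probabilities ~6%/8%/42%), so the whole
pipeline is exercisable and testable at desk scale. See the methods vignette
(`vignettes/cmtc-methods.Rmd`) for the model, parameter meanings and design
rationale.

## Worked example

```r
library(cmtc)

cfg      <- cohort_config(seed = 42)            # 45/65/39 samples, 2000 probes
cohort   <- generate_cohort(cfg)
clinical <- simulate_outcomes(cohort$clinical, cfg)

x   <- preprocess_pipeline(cohort$expr, cohort$annotation)  # qn -> floor -> collapse -> log2 ratio
der <- derive_cmtc(x, clinical)

der$model
#> cmtc_model: 132 features, groups CMTC-1, CMTC-2, CMTC-3
round(der$model$identity_evidence, 3)
#>   cluster her2tn_frac mean_grade er_pos_frac
#> 1       1       0.067      1.867       0.978
#> 2       2       0.077      2.508       0.969
#> 3       3       0.846      2.821       0.077
```

The cluster with 84.6% Her2+/TN tumors becomes CMTC-3; of the rest, the
low-grade, ER-rich cluster becomes CMTC-1. Classifying the same cohort
re-measured on a simulated second platform (80% gene retention, intensity
gain 1.3, offset +50, extra noise):

```r
val <- generate_validation_platform(cohort$expr, cohort$annotation,
                                    platform_spec(), seed = 43)
xv  <- preprocess_pipeline(val$expr, val$annotation)
res <- classify_cohort(der$model, xv)
res
#> cmtc_classification: 149 samples (82% of model genes shared)
#>         group  n      frac
#>        CMTC-1 45 0.3020134
#>        CMTC-2 65 0.4362416
#>        CMTC-3 39 0.2617450
#>  unclassified  0 0.0000000
```

Every sample lands in its planted group despite the platform distortion.
Outcome evaluation uses the assigned labels:

```r
km <- kaplan_meier(clinical, der$labels[clinical$sample_id])
c(chisq = km$logrank_chisq, p = km$p)
#>     chisq         p
#> 13.51...   0.00116...
```

— the three groups separate in relapse-free survival (log-rank p ≈ 0.001),
with group 1 carrying the lowest hazard, as planted.

`run_pipeline(config, out_dir)` executes
simulate → preprocess → derive → classify → evaluate from one YAML config and
writes every artifact plus an md5-hashed run manifest;
`inst/scripts/cmtc` is a thin command-line wrapper over the same functions.

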