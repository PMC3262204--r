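Package: cmtc
Title: ClinicoMolecular Triad Classification of Breast Cancer Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Derives and applies a three-group breast cancer classification
    (CMTC) from bulk expression profiles. Implements microarray intensity
    preprocessing (quantile normalization, intensity flooring, log2 ratio to
    the per-probe mean, probe-to-gene collapsing), a two-screen signature
    derivation anchored on the Her2-positive/triple-negative phenotype
    (Bonferroni-corrected t-test screen, three-way hierarchical clustering,
    ANOVA screen, exclusion of genes overlapping published prognostic
    signatures), a correlation-to-centroid classifier that transfers across
    array platforms, and an outcome-evaluation battery (contingency
    associations, Kaplan-Meier and Cox proportional-hazards relapse analyses,
    endocrine-therapy benefit stratification, and ROC analysis of pathological
    complete response). A seeded synthetic-cohort generator reproduces the
    statistical structure the method assumes, so the whole pipeline is testable
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    limma,
    optparse
Config/testthat/edition: 3
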