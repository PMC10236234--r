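Package: BrainSpare
Title: Multi-Site Harmonization and Machine-Learned Brain-Aging Indices
    for ROI Volume Cohorts
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for cohort studies of brain aging based on regional
    gray-matter volumes measured across many MRI scanners. Implements
    ComBat-GAM location/scale harmonization with empirical-Bayes batch
    effects and a penalized-spline age trend (including a two-step
    within-study then study-to-reference design), machine-learned atrophy
    indices (a support-vector-regression brain-age index and a linear-SVM
    Alzheimer-signature index), a years-equivalent brain-aging statistic
    from mixed models, time-weighted longitudinal risk-factor summaries,
    covariate scans with backward elimination, regional group scans with
    Benjamini-Hochberg FDR control, and cognition-domain associations. A
    synthetic multi-scanner cohort generator with known injected effects
    makes every stage testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    mgcv,
    e1071,
    lme4,
    lmerTest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sva,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
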