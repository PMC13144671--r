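Package: mced
Title: Multimodal Cell-Free DNA Analysis for Multi-Cancer Early Detection
Version: 0.1.0
Authors@R: person("MCED", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements a multimodal cell-free DNA (cfDNA) analysis pipeline
    for multi-cancer early detection: average methylation fraction (AMF)
    quantification over status-homogeneous CpG regions with differential
    methylation and concordance-based marker selection, bin-level copy-number
    markers with healthy-prevalence exclusion rules, fragment size ratio (FSR)
    and fragment size distribution (FSD) fragmentomic features, per-feature
    nine-class classifiers with cross-validated model selection, and a
    logistic cancer-signature ensemble producing specificity-calibrated
    cancer-signal detection calls and weighted tissue-of-origin predictions.
    A seeded synthetic cohort simulator emulating healthy and eight-cancer
    plasma cohorts with stage-dependent tumor fractions makes the entire
    pipeline testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    jsonlite,
    MASS,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
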