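Package: lateRF
Title: Multi-View Late Integration of Multi-Omics Data with AUC-Weighted
    Random Forest Ensembles
Version: 0.1.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classify subjects in small, multi-visit, multi-omics cohorts
    (clinical, 16S genus counts, metaproteomics, immune panels,
    metabolomics) by training one random-forest classifier per data view
    and combining predicted probabilities with AUC-proportional weights
    (late integration).  Includes the bespoke preprocessing the workflow
    needs (robust centered log-ratio transform, left-censored QRILC
    imputation, low-count, limit-of-detection, missingness, near-zero
    variance and correlation filters), grouped stratified train/test
    splitting and cross-validation for repeated measures, class-imbalance
    resampling (random oversampling, SMOTE), decision-threshold selection
    by the geometric mean of per-view sensitivities and specificities,
    greedy forward selection of views, Gini and permutation variable
    importance, and a synthetic multi-view cohort generator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    truncnorm,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
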