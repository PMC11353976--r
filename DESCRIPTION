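Package: tempheno
Title: Temporal Computational Phenotyping of Longitudinal EHR Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering temporal computational phenotypes in
    longitudinal outpatient electronic health record (EHR) data and using them
    to predict clinical outcomes such as a first acute myocardial infarction.
    Provides a synthetic-cohort generator with planted low-rank temporal
    phenotypes and matched case-control construction; EHR cleaning, ICD code
    hierarchy roll-up and train-frozen filtering rules; latest-value, summary
    statistic and patient-by-time-by-feature tensor representations;
    non-negative CP (PARAFAC) decomposition via hierarchical alternating least
    squares with held-out patient projection and rank scanning; minimum
    redundancy maximum relevance feature selection with k-nearest-neighbour
    imputation; a tropical-geometry fuzzy-rule neural network classifier with
    human-readable rule extraction; and evaluation machinery covering
    stratified cross-validation, Platt calibration, reliability curves,
    Friedman and Nemenyi comparisons, and Kendall rank concordance of feature
    importances.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    stats,
    utils,
    zoo,
    rpart,
    ranger,
    glmnet,
    generics
Suggests:
    testthat (>= 3.0.0),
    xgboost,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
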