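Package: ehrisk
Title: Deployment Toolkit for Confidence-Aware EHR Risk-Prediction Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deploying and auditing high-dimensional clinical risk
    prediction models on longitudinal electronic health records (EHR), built
    around a feature-bagged heterogeneous ensemble with soft-vote predictive
    confidence for 2-year composite risk of infection and/or treatment in
    chronic lymphocytic leukemia. Includes a synthetic-EHR cohort generator
    with configurable missingness profiles and source dialects, a temporal
    feature engine with explicit missingness encodings, confidence-stratified
    benchmarking (Matthews correlation, precision/recall, PR-AUC, stratified
    bootstrap, Kaplan-Meier and Cox survival), dictionary-based data
    harmonization validated by prediction matching, a complete-case
    low-dimensional comparator index for prediction-coverage analysis, and
    quarterly drift monitoring with population-stability and
    Kolmogorov-Smirnov shift statistics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    survival,
    xgboost,
    ranger,
    glmnet
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
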