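Package: shapsel
Title: SHAP-Guided Ensemble Feature Ranking and Optimized Forward Selection
    for Clinical Tabular Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid feature-selection toolkit for binary clinical
    classification problems such as coronary artery disease diagnosis.
    Features are ranked by Shapley-value attributions computed for three
    heterogeneous classifiers (gradient-boosted trees, random forest,
    support-vector machine); the per-model ranks are aggregated into an
    ensemble average-rank table which then guides a single-pass sequential
    forward selection wrapper that keeps a candidate feature only when it
    strictly improves cross-validated accuracy, followed by a final check
    on the top-ranked seed feature. Includes exact and coalition-sampling
    Shapley estimators with an enumeration oracle, SMOTE oversampling,
    leakage-safe stratified k-fold evaluation with the standard diagnostic
    metrics, grid search, and a synthetic clinical-table generator with
    planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    xgboost,
    ranger,
    e1071,
    rpart,
    nnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
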