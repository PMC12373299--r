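Package: slecast
Title: Hierarchical Prediction of 12-Month Disease Activity in Systemic Lupus Erythematosus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A contact-level pipeline for predicting a composite 12-month
    disease-activity event from longitudinal systemic lupus erythematosus
    (SLE) records. Implements forward-window composite outcome labeling,
    three-time-range feature engineering with univariate selection,
    a grid-searched main classifier with patient-grouped cross-validation,
    predicted-probability risk stratification, a cascade decision-tree rule
    model on low-confidence contacts, the resulting hierarchical ensemble,
    ROC/AUC evaluation with patient-level bootstrap intervals, and
    Shapley-value explanations. Ships a seeded synthetic longitudinal
    cohort generator emulating the statistical structure of an SLE
    hospital data mart so the whole pipeline runs with no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    glmnet,
    jsonlite,
    purrr,
    ranger,
    Rcpp,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
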