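Package: riskpipe
Title: Ensemble Transfer Learning for Suicide-Risk Prediction from Longitudinal Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A seeded synthetic electronic-medical-record generator with a known
    ground-truth risk model, and the full modelling pipeline it exercises:
    regex-based classification of suicide, suicide-attempt and overdose codes
    with a priority-combined outcome; matched retrospective nested case-control,
    calendar-prospective and event-triggered time-to-event cohort construction
    with date-of-birth partitioning; eight-time-bin longitudinal feature
    encoding with categorical lab/vital imputation; heterogeneous base learners
    (lasso logistic regression, Cox, random forest, feed-forward network,
    naive Bayes) under an even/odd training protocol; ensemble stacking
    fine-tuned by unpenalized logistic regression with design-dependent
    covariates; and evaluation by discrimination, subgroup calibration,
    concentration of risk and temporal-drift comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    lubridate,
    purrr,
    ranger,
    rlang (>= 1.0.0),
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
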