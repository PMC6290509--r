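Package: palliascreen
Title: Palliative-Care Screening from Longitudinal Coded EHR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building 12-month mortality prediction pipelines from
    longitudinal coded electronic health record (EHR) event logs, as used for
    proactive palliative-care screening. Provides a synthetic-EHR generator
    with a planted proportional-hazards mortality mechanism; temporal cohort
    construction with per-patient prediction dates, right-censoring and
    inpatient-admission handling; sparse featurization of ICD9/CPT/RXCUI and
    encounter codes over recency-weighted observation slices with per-category
    summary statistics and demographics; a fully connected SeLU network (or
    logistic baseline) trained with Adam and snapshot-based model selection on
    validation average precision; evaluation for imbalanced probabilistic
    classifiers (average precision, interpolated precision-recall, AUROC,
    Brier score, reliability curves); and counterfactual code-ablation
    explanations of individual predictions.
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
    jsonlite,
    Matrix,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
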