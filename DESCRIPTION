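Package: bagverify
Title: Verification-Bias-Corrected Diagnostic Performance of Ordinal Imaging Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates whole-population diagnostic performance of an ordinal
    imaging score (such as PI-RADS for prostate MRI) when only a biased subset
    of patients has reference-standard pathology. Per-score bootstrap-aggregated
    ensembles of sigmoid-calibrated logistic models estimate the disease
    proportion among unverified patients; fractional-count contingency tables
    convert these into estimated sensitivity, specificity, predictive values,
    cancer detection rate, abnormal interpretation rate, prevalence and ROC/AUC
    with percentile bootstrap confidence intervals. Includes a synthetic
    multi-facility cohort generator with configurable verification mechanisms
    (MAR, MNAR, full verification), chained-equation imputation of missing
    PSA/volume, and forward feature selection with the one-standard-error rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    readr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
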