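Package: neuroqwerty
Title: Keystroke Hold-Time Motor Scores for Early Parkinson's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts raw computer-keyboard key press/release logs into a
    per-subject motor impairment score (the neuroQWERTY index, nQi).
    Hold-time series are partitioned into non-overlapping 90-second windows,
    summarised by seven variance, histogram and key-overlap features, and
    scored by a bagged ensemble of linear epsilon-support-vector regression
    models trained against normalized UPDRS-III motor scores. Includes ROC
    analysis with DeLong confidence intervals and tests, cost-weighted
    generalized Youden cutoff selection, a two-cohort cross-dataset
    validation harness, covariate-adjusted logistic significance tests, and
    a synthetic keystroke-cohort simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
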