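Package: tewsr
Title: Transformer-Based Early Warning Scores for Emergency Department Deterioration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for developing and evaluating transformer-based
    early warning scores (TEWS) on emergency-department event streams: a synthetic
    ED cohort simulator with group-conditional vital-sign and laboratory
    distributions and pre-event deterioration drift; windowed time-series
    preprocessing into 48-hour, 15-minute-resolution tensors with 24-hour-ahead
    adverse-event labels; a single-head transformer encoder risk model with
    class-weighted binary cross-entropy, AdamW training and transfer-learning
    fine-tuning; a Modified Early Warning Score (MEWS) baseline; threshold, alarm
    and bootstrap evaluation; and Grad-CAM-style per-patient attributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    withr,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
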