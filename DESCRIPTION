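Package: emabiscuit
Title: Idiographic Binge-Eating Prediction from Ecological Momentary
    Assessment Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for idiographic (within-person) prediction of binge-eating
    episodes from high-frequency ecological momentary assessment (EMA) data.
    Simulates signal-contingent EMA studies with known ground truth, derives
    the objective binge-eating criterion and time-based predictors (cyclical
    sine/cosine terms and time-of-day indicators), selects parsimonious
    per-person predictor subsets with a correlation-based, cross-validated,
    unit-weighted scale construction algorithm (BISCUIT), and evaluates
    per-person prediction accuracy (empirical AUC with bootstrap confidence
    intervals, Youden-optimal cutoffs, sensitivity, specificity, and
    derivation/validation reliabilities) together with cross-person
    aggregates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
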