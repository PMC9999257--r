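#' Canonical candidate predictor names
#'
#' The candidate set used throughout the package: 31 antecedent EMA items
#' (`item_01` ... `item_31`), the unshifted binge indicator (`binge_now`,
#' the autoregressive predictor), six cyclical time features (sine and
#' cosine of the cumulative assessment time at 8-, 12- and 24-hour
#' periods), and six time-of-day indicators -- 44 predictors in total.
#'
#' @param n_items Number of antecedent EMA items (default 31).
#' @return Character vector of predictor column names, in canonical order.
#'   Canonical order also defines the deterministic tie-break used when two
#'   predictors have equal absolute criterion correlation.
#' @export
#' @examples
#' length(predictor_names())  # 44
predictor_names <- function(n_items = 31L) {
  n_items <- assert_count(n_items, "n_items")
  c(
    sprintf("item_%02d", seq_len(n_items)),
    "binge_now",
    as.vector(t(outer(c("sin", "cos"), c("8h", "12h", "24h"), paste, sep = "_"))),
    paste0("tod_", tod_labels())
  )
}

# Time-of-day labels for the six scheduled slots, in slot order.
tod_labels <- function() {
  c("morning", "late_morning", "early_afternoon",
    "afternoon", "evening", "late_evening")
}

# Meta (non-predictor) columns of a predictor matrix.
matrix_meta_cols <- function() {
  c("participant_id", "timestamp", "day", "slot", "cum_hours",
    "answered", "is_padding")
}
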