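#' Derive the objective binge-eating criterion per prompt
#'
#' An objective binge-eating episode requires both an objectively large
#' amount of food and a sense of loss of control. A prompt is coded 1 when
#' its signal-contingent meal item was answered "binge", or when a
#' qualifying event-contingent report (excessive amount AND loss of
#' control) falls in the prompt's attribution window; 0 when the prompt was
#' answered and neither holds; `NA` when the prompt was unanswered and no
#' qualifying event exists.
#'
#' Event reports are attributed to the scheduled prompt whose window
#' (previous same-day prompt, this prompt] contains their timestamp; the
#' first window of a day opens at midnight, and reports after the last
#' prompt of a day map to that last prompt, so no attribution crosses a day
#' boundary. Reports with a missing excessive-amount or loss-of-control
#' field are rejected with a warning.
#'
#' @param prompts Prompt tibble as in an `ema_participant` (sorted by
#'   timestamp).
#' @param events Event-report tibble (`timestamp`, `excessive_amount`,
#'   `loss_of_control`).
#' @return Integer vector (0/1/`NA`), one element per prompt row.
#' @export
derive_binge_outcomes <- function(prompts, events) {
  if (is.unsorted(prompts$timestamp)) {
    stop("`prompts` must be sorted by timestamp", call. = FALSE)
  }
  bad <- is.na(events$excessive_amount) | is.na(events$loss_of_control)
  if (any(bad)) {
    warning(sprintf("dropping %d event report(s) with missing fields",
                    sum(bad)), call. = FALSE)
    events <- events[!bad, , drop = FALSE]
  }
  qualifying <- logical(nrow(prompts))
  qual_ev <- events[events$excessive_amount == 1 &
                      events$loss_of_control == 1, , drop = FALSE]
  if (nrow(qual_ev) > 0) {
    pdate <- as.Date(prompts$timestamp, tz = "UTC")
    edate <- as.Date(qual_ev$timestamp, tz = "UTC")
    for (d in unique(edate)) {
      in_day <- which(pdate == d)
      if (length(in_day) == 0L) next  # report on a day with no prompts
      ts_day <- as.numeric(prompts$timestamp[in_day])
      ev_day <- as.numeric(qual_ev$timestamp[edate == d])
      idx <- findInterval(ev_day, ts_day, left.open = TRUE) + 1L
      idx <- pmin(idx, length(in_day))
      qualifying[in_day[unique(idx)]] <- TRUE
    }
  }
  out <- ifelse(qualifying, 1L,
                ifelse(prompts$answered,
                       as.integer(!is.na(prompts$meal_type) &
                                    prompts$meal_type == "binge"),
                       NA_integer_))
  as.integer(out)
}

#' Insert an empty padding row after each day's last prompt
#'
#' Keeps the series approximately equally spaced across days and, after
#' [shift_criterion()], prevents any predictor/criterion pair from spanning
#' a day boundary.
#'
#' @param rows Tibble of prompt rows sorted by timestamp, with `day`.
#' @return The input rows plus one all-missing padding row (flagged by the
#'   logical `is_padding` column) after the final prompt of each calendar
#'   day. Original rows are unchanged apart from gaining `is_padding = FALSE`.
#' @export
insert_day_padding <- function(rows) {
  if (nrow(rows) == 0L) {
    rows$is_padding <- logical(0)
    return(rows)
  }
  if (is.unsorted(rows$timestamp)) {
    stop("`rows` must be sorted by timestamp", call. = FALSE)
  }
  rows$is_padding <- FALSE
  split_rows <- split(rows, rows$day)
  padded <- purrr::map(split_rows, function(d) {
    pad <- d[1, ]
    pad[1, ] <- NA
    pad$participant_id <- d$participant_id[1]
    pad$day <- d$day[1]
    pad$is_padding <- TRUE
    if ("answered" %in% names(pad)) pad$answered <- FALSE
    dplyr::bind_rows(d, pad)
  })
  dplyr::bind_rows(padded[order(as.integer(names(padded)))])
}

#' Shift the binge criterion backward by one signal
#'
#' The modelling target `y` at row i is the binge indicator at row i+1, so
#' predictors observed at a prompt are paired with the outcome roughly one
#' inter-prompt interval (2.5 h at the default design) later. Where row i+1
#' is a padding row or absent, `y` is missing: no pair spans a day
#' boundary.
#'
#' @param binge Integer binge indicator (0/1/`NA`) per row, padding
#'   included.
#' @param is_padding Logical padding flag per row.
#' @return Integer vector `y` of the same length.
#' @export
shift_criterion <- function(binge, is_padding) {
  stopifnot(length(binge) == length(is_padding))
  n <- length(binge)
  if (n == 0L) return(integer(0))
  y <- c(binge[-1], NA_integer_)
  nxt_pad <- c(is_padding[-1], TRUE)
  y[nxt_pad] <- NA_integer_
  y[is_padding] <- NA_integer_
  as.integer(y)
}

#' Cyclical time features
#'
#' Sine and cosine of the cumulative assessment time at a given period:
#' `sin(2*pi/period * cum_hours)` and `cos(2*pi/period * cum_hours)`.
#' Cumulative time is the cumulative sum of scheduled inter-prompt
#' differences in hours (0, 2.5, 5, ... at the default design), so the
#' phase is anchored at the first scheduled prompt.
#'
#' @param cum_hours Numeric vector of cumulative hours (>= 0).
#' @param period Cycle period in hours (8, 12 or 24 in the default
#'   predictor set).
#' @return Tibble with columns `sin` and `cos`.
#' @export
#' @examples
#' cyclical_features(c(0, 2.5), 24)
cyclical_features <- function(cum_hours, period) {
  if (!is.numeric(period) || length(period) != 1L || period <= 0) {
    stop("`period` must be a single positive number of hours", call. = FALSE)
  }
  if (any(cum_hours < 0, na.rm = TRUE)) {
    stop("`cum_hours` must be non-negative", call. = FALSE)
  }
  w <- 2 * pi / period * cum_hours
  tibble::tibble(sin = sin(w), cos = cos(w))
}

#' Time-of-day indicator variables
#'
#' One-hot dummy coding of the six scheduled daily slots (morning, late
#' morning, early afternoon, afternoon, evening, late evening); the mapping
#' is positional, slot k to the k-th label.
#'
#' @param slot_index Integer vector of slot positions (1-6; `NA` allowed
#'   and propagated).
#' @return Tibble with six 0/1 columns `tod_morning` ... `tod_late_evening`;
#'   exactly one indicator is 1 per non-missing slot.
#' @export
time_of_day_dummies <- function(slot_index) {
  labs <- tod_labels()
  ok <- is.na(slot_index) | (slot_index %in% seq_along(labs))
  if (!all(ok)) {
    stop("`slot_index` must lie in 1..6", call. = FALSE)
  }
  out <- matrix(NA_integer_, length(slot_index), length(labs),
                dimnames = list(NULL, paste0("tod_", labs)))
  obs <- !is.na(slot_index)
  out[obs, ] <- 0L
  out[cbind(which(obs), slot_index[obs])] <- 1L
  tibble::as_tibble(out)
}

#' Build the candidate predictor matrix for one participant
#'
#' Assembles the full modelling table: the 31 antecedent items, the
#' unshifted binge indicator (`binge_now`, autoregressive predictor), six
#' cyclical features (8-, 12-, 24-hour sine/cosine), six time-of-day
#' dummies, and the time-shifted binary criterion `y_next` -- with one
#' padding row after each day so no predictor/criterion pair crosses a day
#' boundary. Unanswered prompts keep their row: items are missing but the
#' passively collected time features are present, and their criterion can
#' still be defined via event reports.
#'
#' @param dataset An `ema_participant` (simulated or read from disk).
#' @return Tibble with meta columns (`participant_id`, `timestamp`, `day`,
#'   `slot`, `cum_hours`, `answered`, `is_padding`), the 44 predictor
#'   columns of [predictor_names()], and `y_next`.
#' @export
#' @examples
#' m <- build_predictor_matrix(generate_participant(truth_config(seed = 7)))
#' dim(m)  # 84 prompts + 14 padding rows
build_predictor_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "ema_participant"))
  prompts <- dataset$prompts
  n_items <- sum(grepl("^item_\\d+$", names(prompts)))
  pnames <- predictor_names(n_items)
  if (anyDuplicated(pnames)) stop("duplicate predictor names", call. = FALSE)

  base <- prompts
  base$binge_now <- derive_binge_outcomes(prompts, dataset$events)
  padded <- insert_day_padding(base)

  obs <- !padded$is_padding
  cyc <- purrr::map(c(8, 12, 24), function(p) {
    f <- cyclical_features(padded$cum_hours[obs], p)
    out <- tibble::tibble(sin = rep(NA_real_, nrow(padded)),
                          cos = NA_real_)
    out[obs, ] <- f
    names(out) <- paste0(c("sin_", "cos_"), p, "h")
    out
  })
  tod <- time_of_day_dummies(padded$slot)

  out <- dplyr::bind_cols(
    padded[, c(matrix_meta_cols()[matrix_meta_cols() %in% names(padded)])],
    padded[, grepl("^item_\\d+$", names(padded))],
    padded["binge_now"], cyc, tod)
  out <- out[, c(matrix_meta_cols(), pnames)]
  out$y_next <- shift_criterion(out$binge_now, out$is_padding)
  out
}

#' Write / read a predictor matrix as CSV
#'
#' Round-trips the output of [build_predictor_matrix()] including the
#' padding flag and `y_next` criterion column.
#'
#' @param m Predictor-matrix tibble.
#' @param path CSV file path.
#' @export
write_predictor_matrix <- function(m, path) {
  readr::write_csv(m, path, na = "")
  invisible(path)
}

#' @rdname write_predictor_matrix
#' @export
read_predictor_matrix <- function(path) {
  m <- readr::read_csv(
    path, show_col_types = FALSE, na = "",
    col_types = readr::cols(participant_id = "c", timestamp = "T",
                            answered = "l", is_padding = "l",
                            .default = "d"))
  for (col in c("day", "slot", "binge_now", "y_next",
                grep("^tod_", names(m), value = TRUE))) {
    m[[col]] <- as.integer(m[[col]])
  }
  m
}
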