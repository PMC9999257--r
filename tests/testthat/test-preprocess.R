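test_that("objective binge criterion combines meal item and event reports", {
  # day of 3 prompts at 08:00, 10:30, 13:00; binge meal at slot 2
  prompts <- make_prompts(list(c(0, 1, 0)))
  expect_equal(derive_binge_outcomes(prompts, no_events()), c(0L, 1L, 0L))

  ev <- function(hhmm, exc, loc) tibble::tibble(
    participant_id = "T1",
    timestamp = as.POSIXct(paste("2024-03-01", hhmm), tz = "UTC"),
    excessive_amount = exc, loss_of_control = loc)

  base <- make_prompts(list(c(0, 0, 0)))
  # qualifying report (excessive AND loss of control) in (08:00, 10:30]
  expect_equal(derive_binge_outcomes(base, ev("09:15", 1L, 1L)),
               c(0L, 1L, 0L))
  # one criterion alone does not qualify
  expect_equal(derive_binge_outcomes(base, ev("09:15", 1L, 0L)),
               c(0L, 0L, 0L))
  expect_equal(derive_binge_outcomes(base, ev("09:15", 0L, 1L)),
               c(0L, 0L, 0L))
  # window boundary: a report exactly at a prompt belongs to that prompt
  expect_equal(derive_binge_outcomes(base, ev("10:30", 1L, 1L)),
               c(0L, 1L, 0L))
  # after the last prompt of the day -> attributed to the last prompt
  expect_equal(derive_binge_outcomes(base, ev("22:00", 1L, 1L)),
               c(0L, 0L, 1L))
  # before the first prompt -> first prompt (same day)
  expect_equal(derive_binge_outcomes(base, ev("06:00", 1L, 1L)),
               c(1L, 0L, 0L))
  # malformed report is rejected with a warning
  expect_warning(
    out <- derive_binge_outcomes(base, ev("09:15", NA_integer_, 1L)),
    "missing fields")
  expect_equal(out, c(0L, 0L, 0L))
})

test_that("unanswered prompts are missing unless an event qualifies", {
  prompts <- make_prompts(list(c(0, NA, 0)))
  expect_equal(derive_binge_outcomes(prompts, no_events()),
               c(0L, NA_integer_, 0L))
  ev <- tibble::tibble(
    participant_id = "T1",
    timestamp = as.POSIXct("2024-03-01 10:00", tz = "UTC"),
    excessive_amount = 1L, loss_of_control = 1L)
  expect_equal(derive_binge_outcomes(prompts, ev), c(0L, 1L, 0L))
})

test_that("day padding adds exactly one all-missing row per day", {
  two_days <- make_prompts(list(rep(0, 6), rep(0, 6)))
  padded <- insert_day_padding(two_days)
  expect_equal(nrow(padded), 14)
  expect_equal(sum(padded$is_padding), 2)
  expect_true(all(which(padded$is_padding) == c(7, 14)))
  pad_rows <- padded[padded$is_padding, ]
  expect_true(all(is.na(pad_rows$item_01)))
  expect_true(all(is.na(pad_rows$timestamp)))
  # original rows unchanged
  expect_equal(padded$item_02[!padded$is_padding], two_days$item_02)

  one_day <- insert_day_padding(make_prompts(list(rep(0, 6))))
  expect_equal(nrow(one_day), 7)

  empty <- two_days[0, ]
  expect_equal(nrow(insert_day_padding(empty)), 0)

  shuffled <- two_days[c(2, 1, 3:12), ]
  expect_error(insert_day_padding(shuffled), "sorted")
})

test_that("criterion shift pairs each row with the next same-day binge", {
  # within one day
  pad1 <- c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  expect_equal(shift_criterion(c(0L, 0L, 1L, 0L, 0L, 0L, NA), pad1),
               c(0L, 1L, 0L, 0L, 0L, NA, NA))
  # single-prompt day
  expect_equal(shift_criterion(c(0L, NA), c(FALSE, TRUE)),
               c(NA_integer_, NA_integer_))
  # two days [0,1 | 1,0] -> y = [1, NA, 0, NA] (padding rows dropped here)
  y <- shift_criterion(c(0L, 1L, NA, 1L, 0L, NA),
                       c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(y[!c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE)],
               c(1L, NA, 0L, NA))
  expect_equal(shift_criterion(integer(0), logical(0)), integer(0))
})

test_that("cyclical features follow the sinusoid formula", {
  expect_equal(cyclical_features(0, 24), tibble::tibble(sin = 0, cos = 1))
  half <- cyclical_features(6, 12)
  expect_equal(half$sin, 0, tolerance = 1e-12)
  expect_equal(half$cos, -1)
  at25 <- cyclical_features(2.5, 24)
  expect_equal(at25$sin, 0.608761, tolerance = 1e-6)
  expect_equal(at25$cos, 0.793353, tolerance = 1e-6)
  expect_error(cyclical_features(1, 0), "positive")
  expect_error(cyclical_features(-1, 24), "non-negative")
})

test_that("time-of-day dummies are one-hot over the six slots", {
  d1 <- time_of_day_dummies(1)
  expect_equal(d1$tod_morning, 1L)
  expect_equal(sum(d1), 1)
  d6 <- time_of_day_dummies(6)
  expect_equal(d6$tod_late_evening, 1L)
  all_slots <- time_of_day_dummies(1:6)
  expect_equal(rowSums(all_slots), rep(1, 6))
  expect_equal(colSums(all_slots), setNames(rep(1, 6), names(all_slots)))
  expect_error(time_of_day_dummies(7), "1..6")
  expect_true(all(is.na(time_of_day_dummies(NA_integer_))))
})

test_that("predictor matrix has the documented shape and padding semantics", {
  p <- generate_participant(truth_config(seed = 8L))
  m <- build_predictor_matrix(p)
  expect_equal(nrow(m), 84 + 14)
  expect_true(all(predictor_names() %in% names(m)))
  expect_equal(length(predictor_names()), 44)
  # padding rows: all predictors and y missing
  pad <- m[m$is_padding, predictor_names()]
  expect_true(all(is.na(pad)))
  expect_true(all(is.na(m$y_next[m$is_padding])))
  # last prompt of each day (the row before padding) has missing y
  last_of_day <- !m$is_padding & c(m$is_padding[-1], TRUE)
  expect_true(all(is.na(m$y_next[last_of_day])))
  # sin^2 + cos^2 = 1 on every non-padding row
  obs <- !m$is_padding
  for (per in c("8h", "12h", "24h")) {
    expect_equal(m[[paste0("sin_", per)]][obs]^2 +
                   m[[paste0("cos_", per)]][obs]^2,
                 rep(1, sum(obs)), tolerance = 1e-12)
  }
  # time features exist even on unanswered rows; items do not
  un <- obs & !m$answered
  expect_true(all(!is.na(m$sin_24h[un])))
  expect_true(all(is.na(m$item_01[un])))
  # no criterion pair spans a day boundary
  has_y <- which(!is.na(m$y_next))
  expect_true(all(m$day[has_y + 1L] == m$day[has_y]))
  expect_equal(m$y_next[has_y], m$binge_now[has_y + 1L])
})

test_that("a no-binge dataset yields an all-zero autoregressive column", {
  p <- generate_participant(truth_config(seed = 9L, beta0 = -20,
                                         item_effects = numeric(0)))
  m <- build_predictor_matrix(p)
  expect_true(all(m$binge_now[!m$is_padding & m$answered] == 0))
  expect_true(all(m$y_next %in% c(0L, NA_integer_)))
})

test_that("predictor matrix round-trips through CSV", {
  p <- generate_participant(truth_config(seed = 10L))
  m <- build_predictor_matrix(p)
  path <- withr::local_tempfile(fileext = ".csv")
  write_predictor_matrix(m, path)
  m2 <- read_predictor_matrix(path)
  expect_equal(names(m2), names(m))
  expect_equal(m2$y_next, m$y_next)
  expect_equal(m2$is_padding, m$is_padding)
  expect_equal(m2$sin_12h, m$sin_12h, tolerance = 1e-12)
  expect_equal(m2$item_17, m$item_17, tolerance = 1e-12)
})
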