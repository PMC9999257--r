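#' Published pilot-cohort model-fit indices
#'
#' The per-participant model-fit indices reported for a published pilot
#' cohort of 13 female patients with bulimia nervosa or binge-eating
#' disorder, whose next-2.5-hour binge-eating episodes were predicted from
#' idiographic BISCUIT-selected EMA predictor subsets: AUC with bootstrap
#' 95% CI, in-sample specificity and sensitivity at the optimal cutoff, and
#' the fold-wise mean (SD) of the derivation reliability r_D and the
#' cross-validated reliability r_CV. Useful as a reference input for
#' [aggregate_results()] and for benchmarking simulated cohorts.
#'
#' @return Tibble with 13 rows and columns `participant_id`, `auc`,
#'   `ci_lower`, `ci_upper`, `specificity`, `sensitivity`, `r_d_mean`,
#'   `r_d_sd`, `r_cv_mean`, `r_cv_sd`.
#' @export
#' @examples
#' aggregate_results(pilot_cohort_results())
pilot_cohort_results <- function() {
  tibble::tibble(
    participant_id = sprintf("%02d", 1:13),
    auc = c(0.92, 0.97, 0.84, 0.51, 0.73, 0.93, 0.93,
            0.85, 0.63, 0.75, 0.72, 0.60, 0.98),
    ci_lower = c(0.75, 0.92, 0.70, 0.23, 0.45, 0.77, 0.83,
                 0.75, 0.41, 0.58, 0.53, 0.29, 0.94),
    ci_upper = c(1.00, 1.00, 0.98, 0.80, 1.00, 1.00, 1.00,
                 0.95, 0.85, 0.93, 0.92, 0.90, 1.00),
    specificity = c(0.84, 0.89, 0.74, 1.00, 0.86, 0.85, 0.90,
                    0.81, 1.00, 0.74, 0.87, 0.91, 0.96),
    sensitivity = c(1.00, 1.00, 0.86, 0.45, 0.67, 1.00, 1.00,
                    0.80, 0.56, 0.73, 0.69, 0.56, 1.00),
    r_d_mean = c(0.48, 0.42, 0.53, 0.33, 0.34, 0.47, 0.53,
                 0.51, 0.10, 0.46, 0.50, 0.18, 0.32),
    r_d_sd = c(0.04, 0.05, 0.04, 0.05, 0.03, 0.06, 0.06,
               0.10, 0.22, 0.06, 0.06, 0.10, 0.23),
    r_cv_mean = c(0.41, 0.10, -0.02, 0.36, 0.38, -0.36, 0.29,
                  0.54, -0.11, 0.34, 0.27, 0.08, -0.56),
    r_cv_sd = c(0.34, 0.56, 0.72, 0.38, 0.62, 0.28, 0.30,
                0.42, 0.46, 0.64, 0.64, 0.78, 0.57)
  )
}

# Metrics aggregated across participants, in reporting order.
cohort_metrics <- function() {
  c("auc", "ci_lower", "ci_upper", "sensitivity", "specificity",
    "r_d_mean", "r_cv_mean", "k")
}

#' Aggregate per-participant results into cohort statistics
#'
#' Arithmetic mean and sample SD (n - 1 denominator) of each accuracy
#' metric across participants, computed over the participants for whom the
#' metric is defined. The confidence-interval bounds are averaged
#' endpoint-wise (mean of lower bounds, mean of upper bounds). With a
#' single participant the SD is reported as missing.
#'
#' @param results A tibble of per-participant results (rows as produced by
#'   [evaluate_participant()] or [pilot_cohort_results()]) or a list of
#'   such one-row tibbles.
#' @return Tibble with one row per available metric: `metric`, `mean`,
#'   `sd`, `n_used`, plus the attribute `n_participants`.
#' @export
aggregate_results <- function(results) {
  if (is.list(results) && !is.data.frame(results)) {
    results <- dplyr::bind_rows(results)
  }
  if (!is.data.frame(results) || nrow(results) == 0L) {
    stop("`results` must contain at least one participant", call. = FALSE)
  }
  metrics <- intersect(cohort_metrics(), names(results))
  out <- purrr::map_dfr(metrics, function(mt) {
    v <- results[[mt]][!is.na(results[[mt]])]
    tibble::tibble(metric = mt,
                   mean = if (length(v)) mean(v) else NA_real_,
                   sd = sample_sd(v),
                   n_used = length(v))
  })
  attr(out, "n_participants") <- nrow(results)
  out
}

#' Participants-by-predictors selection matrix
#'
#' The cohort view of the idiographic selections: one row per participant,
#' one column per candidate predictor (canonical order), each cell the
#' signed criterion correlation of a selected predictor and `NA` where the
#' predictor was not selected. With `stars = TRUE` cells are formatted as
#' character strings with unadjusted two-tailed significance markers
#' (`*` p < .05, `**` p < .01, `***` p < .001, from the t approximation of
#' a Pearson correlation at its pairwise-complete n).
#'
#' @param results Tibble (or list) of per-participant results carrying the
#'   `selection` list-column of [evaluate_participant()].
#' @param stars Annotate significance (default `FALSE`, numeric cells).
#' @return Tibble: `participant_id` plus one column per predictor ever
#'   selected, in canonical predictor order.
#' @export
selection_matrix <- function(results, stars = FALSE) {
  if (is.list(results) && !is.data.frame(results)) {
    results <- dplyr::bind_rows(results)
  }
  if (!is.data.frame(results) || nrow(results) == 0L) {
    stop("`results` must contain at least one participant", call. = FALSE)
  }
  long <- tidyr::unnest(results[, c("participant_id", "selection")],
                        "selection")
  if (stars) {
    p <- correlation_p_value(long$r, long$n_pairs)
    long$cell <- paste0(sprintf("%+.2f", long$r),
                        ifelse(is.na(p), "",
                               ifelse(p < .001, "***",
                                      ifelse(p < .01, "**",
                                             ifelse(p < .05, "*", "")))))
  } else {
    long$cell <- long$r
  }
  wide <- tidyr::pivot_wider(long[, c("participant_id", "predictor", "cell")],
                             names_from = "predictor",
                             values_from = "cell")
  ord <- intersect(predictor_names(), names(wide))
  wide[, c("participant_id", ord)]
}

# Two-tailed p value of a Pearson correlation from the t approximation.
correlation_p_value <- function(r, n) {
  df <- n - 2
  t <- abs(r) * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(t, df, lower.tail = FALSE)
  p[df < 1] <- NA_real_
  p
}

#' Run the full idiographic prediction pipeline
#'
#' Simulate (or ingest) a cohort, build each participant's predictor
#' matrix, select the idiographic predictor subset with
#' [biscuit_select()], evaluate it with [evaluate_participant()], and
#' write the reporting artifacts: `table1.csv` (per-participant metrics),
#' `summary.json` (cohort means/SDs), `selection_matrix.csv`, and
#' `run_log.txt` (seeds and per-participant status). Participants whose
#' selection or evaluation fails (e.g. too few episodes) are logged,
#' warned about, and excluded from aggregation.
#'
#' @param config List with elements `mode` (`"simulate"`, default, or
#'   `"ingest"`); for simulate: `truth` (a [truth_config()]) and
#'   `n_participants`; for ingest: `datasets`, a list of
#'   `ema_participant` objects (e.g. from [read_ema_dataset()]); and
#'   optionally `n_folds` (10), `k_max` (20), `bootstrap_B` (2000),
#'   `stratify` (TRUE).
#' @param out_dir Output directory; `NULL` to skip writing files.
#' @param seed Master seed driving simulation, fold assignment and
#'   bootstrap.
#' @return List with `results` (per-participant tibble), `summary`
#'   (cohort tibble from [aggregate_results()]), `selection` (matrix
#'   tibble), invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, seed = 1L) {
  mode <- config$mode %||% "simulate"
  n_folds <- config$n_folds %||% 10L
  k_max <- config$k_max %||% 20L
  B <- config$bootstrap_B %||% 2000L
  stratify <- config$stratify %||% TRUE

  if (mode == "simulate") {
    truth <- config$truth %||% truth_config()
    n_participants <- config$n_participants %||% 13L
    if (n_participants < 1L) {
      stop("`n_participants` must be at least 1", call. = FALSE)
    }
    datasets <- generate_cohort(truth, n_participants, seed = seed)
  } else if (mode == "ingest") {
    datasets <- config$datasets
    if (is.null(datasets) || length(datasets) == 0L) {
      stop("ingest mode needs a non-empty `datasets` list", call. = FALSE)
    }
  } else {
    stop("`mode` must be \"simulate\" or \"ingest\"", call. = FALSE)
  }

  fit_seeds <- derive_seeds(seed + 1L, length(datasets))
  log_lines <- c(sprintf("master seed: %d", seed),
                 sprintf("mode: %s; participants: %d", mode, length(datasets)))
  results <- list()
  for (i in seq_along(datasets)) {
    id <- datasets[[i]]$prompts$participant_id[1]
    res <- tryCatch({
      m <- build_predictor_matrix(datasets[[i]])
      scale <- suppressWarnings(
        biscuit_select(m, n_folds = n_folds,
                       k_grid = seq_len(k_max), seed = fit_seeds[i],
                       stratify = stratify))
      evaluate_participant(m, scale, B = B, seed = fit_seeds[i])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("participant %s excluded: %s", id, conditionMessage(res)),
              call. = FALSE)
      log_lines <- c(log_lines,
                     sprintf("%s: EXCLUDED (%s)", id, conditionMessage(res)))
    } else {
      results[[length(results) + 1L]] <- res
      log_lines <- c(log_lines,
                     sprintf("%s: ok (seed %d, k = %d, AUC %.3f)",
                             id, fit_seeds[i], res$k, res$auc))
    }
  }
  if (length(results) == 0L) {
    stop("no participant could be evaluated", call. = FALSE)
  }
  results <- dplyr::bind_rows(results)
  summary <- aggregate_results(results)
  selection <- selection_matrix(results)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(dplyr::select(results, -"selection"),
                     file.path(out_dir, "table1.csv"))
    jsonlite::write_json(
      list(n_participants = nrow(results),
           metrics = as.data.frame(summary)),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
    readr::write_csv(selection, file.path(out_dir, "selection_matrix.csv"),
                     na = "")
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  invisible(list(results = results, summary = summary, selection = selection))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
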