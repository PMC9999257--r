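#' Empirical area under the ROC curve
#'
#' AUC as the probability that a randomly chosen positive outscores a
#' randomly chosen negative, with ties counted half:
#' `P(s+ > s-) + 0.5 * P(s+ = s-)` over all positive-negative pairs.
#' Computed via the rank (Mann-Whitney) identity, which handles ties
#' exactly. Rows with a missing score or outcome are dropped first.
#'
#' @param scores Numeric risk scores.
#' @param y Binary outcome (0/1).
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc_empirical(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
auc_empirical <- function(scores, y) {
  ok <- !is.na(scores) & !is.na(y)
  scores <- scores[ok]
  y <- y[ok]
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC undefined: need at least one positive and one negative ",
         "with a non-missing score", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Stratified percentile bootstrap CI for the AUC
#'
#' Resamples positives and negatives with replacement within class (so
#' every resample has both classes), recomputes the empirical AUC, and
#' returns the percentile interval. Resamples with an undefined AUC are
#' skipped; more than 50% degenerate resamples is an error.
#'
#' @inheritParams auc_empirical
#' @param B Number of bootstrap resamples (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Seed; with a fixed seed the interval is reproducible.
#' @return Numeric `c(lower, upper)`.
#' @export
bootstrap_auc_ci <- function(scores, y, B = 2000L, level = 0.95, seed = 1L) {
  B <- assert_count(B, "B")
  assert_prob(level, "level")
  ok <- !is.na(scores) & !is.na(y)
  scores <- scores[ok]
  y <- y[ok]
  auc_empirical(scores, y)  # errors if undefined on the sample
  pos <- which(y == 1)
  neg <- which(y == 0)
  aucs <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- c(sample(pos, length(pos), replace = TRUE),
               sample(neg, length(neg), replace = TRUE))
      auc_empirical(scores[idx], y[idx])
    }, numeric(1))
  })
  if (mean(is.na(aucs)) > 0.5) {
    stop("more than half of the bootstrap resamples were degenerate",
         call. = FALSE)
  }
  alpha <- 1 - level
  stats::quantile(aucs, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE,
                  names = FALSE)
}

#' Youden-optimal classification cutoff
#'
#' Scans every midpoint between adjacent distinct score values plus the
#' two infinite endpoints, classifying a row positive when
#' `score >= cutoff`, and returns the cutoff maximizing Youden's J
#' (sensitivity + specificity - 1). Because the all-positive and
#' all-negative rules are always candidates, the returned J is never
#' negative. Ties in J break toward the smallest cutoff, favoring
#' sensitivity (for a just-in-time intervention a missed episode is
#' costlier than a false alarm).
#'
#' @inheritParams auc_empirical
#' @return List with `cutoff`, `sensitivity`, `specificity`, `j`.
#' @export
optimal_cutoff <- function(scores, y) {
  ok <- !is.na(scores) & !is.na(y)
  scores <- scores[ok]
  y <- y[ok]
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  if (n_pos == 0L || n_neg == 0L) {
    stop("cutoff undefined: need both classes present", call. = FALSE)
  }
  s <- sort(unique(scores))
  cands <- c(-Inf, if (length(s) > 1L) (s[-1] + s[-length(s)]) / 2, Inf)
  sens <- vapply(cands, function(ct) sum(scores >= ct & y == 1) / n_pos,
                 numeric(1))
  spec <- vapply(cands, function(ct) sum(scores < ct & y == 0) / n_neg,
                 numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)[1]  # smallest cutoff among the ties
  list(cutoff = cands[best], sensitivity = sens[best],
       specificity = spec[best], j = j[best])
}

#' Evaluate a selected scale on a participant's data
#'
#' Scores every row with an observed criterion via [unit_weighted_score()]
#' and assembles the per-participant accuracy record: empirical AUC with a
#' stratified percentile bootstrap 95% CI, the Youden-optimal cutoff with
#' its sensitivity and specificity (in-sample, as reported), the fold-wise
#' derivation and cross-validated reliabilities of the scale, and the
#' participant's answered-prompt and binge-episode counts.
#'
#' @param m Predictor matrix from [build_predictor_matrix()].
#' @param scale A `biscuit_scale` (normally fitted on the same matrix).
#' @param B Bootstrap resamples for the AUC CI (default 2000).
#' @param seed Bootstrap seed.
#' @param level Confidence level of the bootstrap interval.
#' @return One-row tibble with columns `participant_id`, `n_answered`,
#'   `n_binges`, `auc`, `ci_lower`, `ci_upper`, `cutoff`, `sensitivity`,
#'   `specificity`, `r_d_mean`, `r_d_sd`, `r_cv_mean`, `r_cv_sd`, `k`, and
#'   the list-column `selection` (tibble of selected predictors with keys,
#'   correlations and pairwise n).
#' @export
evaluate_participant <- function(m, scale, B = 2000L, seed = 1L,
                                 level = 0.95) {
  stopifnot(inherits(scale, "biscuit_scale"))
  scores <- unit_weighted_score(m, scale)
  ok <- !is.na(m$y_next) & !is.na(scores)
  s <- scores[ok]
  y <- m$y_next[ok]
  auc <- auc_empirical(s, y)
  ci <- bootstrap_auc_ci(s, y, B = B, level = level, seed = seed)
  cut <- optimal_cutoff(s, y)
  rel <- summarize_reliability(scale)
  id <- m$participant_id[!is.na(m$participant_id)][1]
  tibble::tibble(
    participant_id = if (is.na(id)) "unknown" else id,
    n_answered = sum(m$answered & !m$is_padding, na.rm = TRUE),
    n_binges = sum(m$binge_now == 1, na.rm = TRUE),
    auc = auc,
    ci_lower = ci[1], ci_upper = ci[2],
    cutoff = cut$cutoff,
    sensitivity = cut$sensitivity, specificity = cut$specificity,
    r_d_mean = rel$r_d_mean, r_d_sd = rel$r_d_sd,
    r_cv_mean = rel$r_cv_mean, r_cv_sd = rel$r_cv_sd,
    k = scale$k,
    selection = list(tibble::tibble(predictor = scale$predictors,
                                    key = scale$keys, r = scale$r,
                                    n_pairs = scale$n_pairs))
  )
}
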