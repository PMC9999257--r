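#' Pairwise-complete Pearson correlation with the criterion
#'
#' Pearson correlation over jointly observed pairs (equivalently the
#' point-biserial correlation when `y` is binary). Undefined correlations
#' -- fewer than three complete pairs, or either series constant on the
#' joint support -- are returned as `NA` with a warning, which excludes the
#' predictor from ranking.
#'
#' @param x Numeric predictor series (missing values allowed).
#' @param y Criterion series (missing values allowed).
#' @param min_pairs Minimum number of complete pairs (default 3).
#' @return A single correlation, or `NA`.
#' @export
#' @examples
#' pairwise_pearson(c(1, 2, 3, 4), c(0, 0, 1, 1))  # 0.894427
pairwise_pearson <- function(x, y, min_pairs = 3L) {
  r <- pairwise_pearson_quiet(x, y, min_pairs)
  if (is.na(r)) {
    warning("correlation undefined (constant series or < ", min_pairs,
            " complete pairs); returning NA", call. = FALSE)
  }
  r
}

# Same, without the warning; used for ranking many predictors at once.
pairwise_pearson_quiet <- function(x, y, min_pairs = 3L) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_pairs) return(NA_real_)
  x <- x[ok]
  y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# Correlations of every column of X with y; returns r and the pairwise n.
rank_correlations <- function(X, y, min_pairs = 3L) {
  r <- apply(X, 2, pairwise_pearson_quiet, y = y, min_pairs = min_pairs)
  n <- colSums(!is.na(X) & !is.na(y))
  tibble::tibble(predictor = colnames(X), r = unname(r), n_pairs = unname(n))
}

#' Score rows on a unit-weighted scale
#'
#' Each keyed predictor is standardized with the mean/SD stored in the
#' scale (estimated on its derivation rows), multiplied by its key (+1 or
#' -1), and the score is the mean over the keyed predictors observed in the
#' row -- prorated unit weighting, which is what makes the method robust to
#' missing data. Rows where every keyed predictor is missing score `NA`.
#'
#' @param newdata Predictor-matrix tibble (or any data frame containing the
#'   scale's predictor columns).
#' @param scale A `biscuit_scale` from [biscuit_select()].
#' @return Numeric score per row.
#' @export
unit_weighted_score <- function(newdata, scale) {
  stopifnot(inherits(scale, "biscuit_scale"))
  score_rows(as.matrix(newdata[, scale$predictors, drop = FALSE]),
             scale$keys, scale$mu, scale$sigma)
}

score_rows <- function(X, keys, mu, sigma) {
  sigma[!is.na(sigma) & sigma == 0] <- NA_real_  # degenerate item: no signal
  z <- sweep(sweep(X, 2, mu, "-"), 2, sigma, "/")
  keyed <- sweep(z, 2, keys, "*")
  n_obs <- rowSums(!is.na(keyed))
  out <- rowMeans(keyed, na.rm = TRUE)
  out[n_obs == 0L] <- NA_real_
  out
}

# Stratified (or plain) seeded fold assignment over indices 1..n.
assign_folds <- function(y, n_folds, stratify = TRUE, seed = 1L) {
  n <- length(y)
  with_seed(seed, {
    folds <- integer(n)
    if (stratify) {
      for (cls in unique(y)) {
        idx <- sample(which(y == cls))
        folds[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
    } else {
      folds[sample.int(n)] <- rep_len(seq_len(n_folds), n)
    }
    folds
  })
}

# Build a candidate scale (top-k by |r|) from a ranking table and derivation
# rows; ties in |r| break by canonical column order (stable sort).
top_k_scale <- function(ranking, k, X_train) {
  usable <- which(!is.na(ranking$r))
  ord <- usable[order(-abs(ranking$r[usable]))]  # order() is stable
  sel <- ord[seq_len(min(k, length(ord)))]
  predictors <- ranking$predictor[sel]
  Xs <- X_train[, predictors, drop = FALSE]
  list(predictors = predictors,
       keys = sign(ranking$r[sel]),
       r = ranking$r[sel],
       n_pairs = ranking$n_pairs[sel],
       mu = colMeans(Xs, na.rm = TRUE),
       sigma = apply(Xs, 2, stats::sd, na.rm = TRUE))
}

#' Select an idiographic predictor subset (BISCUIT)
#'
#' From-scratch implementation of the Best Items Scale that is
#' Cross-validated, Unit-weighted, Informative and Transparent algorithm.
#' For each cross-validation fold, every candidate predictor is correlated
#' (pairwise-complete Pearson) with the time-shifted binge criterion on the
#' derivation rows; for each candidate size k the top-k predictors by |r|
#' form a unit-weighted scale (keys = sign of r, standardization from the
#' derivation rows only), whose correlation with the criterion is recorded
#' on the derivation rows (r_D) and the held-out rows (r_CV). The size with
#' the highest mean cross-validated correlation is retained and the final
#' scale is refit on all usable rows at that size.
#'
#' Folds are a seeded random partition of the rows with a non-missing
#' criterion, stratified by the criterion by default so every fold sees
#' positive cases even for participants with very few episodes
#' (`stratify = FALSE` restores plain X-fold CV). A fold whose held-out
#' correlation is undefined (e.g. no positive case) is recorded as missing
#' with a warning and excluded from the fold average. With a fixed seed the
#' fold assignment and output are bit-reproducible.
#'
#' @param m Predictor matrix from [build_predictor_matrix()] (or any tibble
#'   with the predictor columns and `y_next`).
#' @param n_folds Number of cross-validation folds (default 10).
#' @param k_grid Candidate scale sizes; default 1 up to 20 (capped at the
#'   number of rankable predictors).
#' @param seed Seed for the fold assignment.
#' @param stratify Stratify folds by the criterion (default `TRUE`).
#' @return A `biscuit_scale`: `predictors`, `keys`, chosen `k`, per-item
#'   full-sample correlations `r` and pairwise `n_pairs`, standardization
#'   parameters `mu`/`sigma`, and `diagnostics` (full ranking table, the
#'   per-fold r_D/r_CV at the chosen size, and the evaluated k grid with
#'   mean cross-validated correlation per size).
#' @export
biscuit_select <- function(m, n_folds = 10L, k_grid = NULL, seed = 1L,
                           stratify = TRUE) {
  n_folds <- assert_count(n_folds, "n_folds", min = 2L)
  pnames <- intersect(predictor_names(sum(grepl("^item_\\d+$", names(m)))),
                      names(m))
  usable <- which(!is.na(m$y_next))
  X <- as.matrix(m[usable, pnames, drop = FALSE])
  y <- m$y_next[usable]
  if (length(unique(y)) < 2L) {
    stop("criterion has fewer than two distinct observed values; ",
         "cannot select predictors", call. = FALSE)
  }
  if (sum(y == 1) < 2L || sum(y == 0) < 2L) {
    stop("need at least 2 binge and 2 non-binge rows with observed criterion",
         call. = FALSE)
  }
  if (is.null(k_grid)) k_grid <- seq_len(min(20L, length(pnames)))
  if (any(k_grid < 1L)) stop("`k_grid` sizes must be >= 1", call. = FALSE)
  k_grid <- sort(unique(as.integer(k_grid)))

  folds <- assign_folds(y, n_folds, stratify = stratify, seed = seed)
  fold_ids <- sort(unique(folds))
  r_d <- matrix(NA_real_, length(fold_ids), length(k_grid),
                dimnames = list(fold_ids, k_grid))
  r_cv <- r_d
  degenerate_folds <- 0L
  for (f in seq_along(fold_ids)) {
    tr <- folds != fold_ids[f]
    ranking <- rank_correlations(X[tr, , drop = FALSE], y[tr])
    if (all(is.na(ranking$r))) next
    for (j in seq_along(k_grid)) {
      sc <- top_k_scale(ranking, k_grid[j], X[tr, , drop = FALSE])
      s_tr <- score_rows(X[tr, sc$predictors, drop = FALSE],
                         sc$keys, sc$mu, sc$sigma)
      s_va <- score_rows(X[!tr, sc$predictors, drop = FALSE],
                         sc$keys, sc$mu, sc$sigma)
      r_d[f, j] <- pairwise_pearson_quiet(s_tr, y[tr])
      r_cv[f, j] <- pairwise_pearson_quiet(s_va, y[!tr])
    }
    if (all(is.na(r_cv[f, ]))) degenerate_folds <- degenerate_folds + 1L
  }
  if (degenerate_folds > 0L) {
    warning(sprintf(
      "%d fold(s) had an undefined held-out correlation (recorded as missing)",
      degenerate_folds), call. = FALSE)
  }
  mean_cv <- colMeans(r_cv, na.rm = TRUE)
  mean_cv[is.nan(mean_cv)] <- NA_real_
  if (all(is.na(mean_cv))) {
    stop("cross-validated correlation undefined for every candidate size",
         call. = FALSE)
  }
  best_j <- which.max(mean_cv)  # ties: smallest (most parsimonious) size
  k_star <- k_grid[best_j]

  ranking_all <- rank_correlations(X, y)
  final <- top_k_scale(ranking_all, k_star, X)
  structure(
    list(predictors = final$predictors,
         keys = final$keys,
         k = length(final$predictors),
         r = final$r,
         n_pairs = final$n_pairs,
         mu = final$mu,
         sigma = final$sigma,
         n_folds = n_folds,
         seed = seed,
         diagnostics = list(
           ranking = ranking_all,
           fold_r_d = unname(r_d[, best_j]),
           fold_r_cv = unname(r_cv[, best_j]),
           k_table = tibble::tibble(k = k_grid,
                                    mean_r_cv = unname(mean_cv)))),
    class = "biscuit_scale")
}

#' @export
print.biscuit_scale <- function(x, ...) {
  rel <- summarize_reliability(x)
  cat(sprintf("<biscuit_scale: k = %d predictors>\n", x$k))
  for (i in seq_len(x$k)) {
    cat(sprintf("  %s%-16s r = %+.3f (n = %d)\n",
                ifelse(x$keys[i] > 0, "+", "-"), x$predictors[i],
                x$r[i], x$n_pairs[i]))
  }
  cat(sprintf("  r_D %.2f (SD %.2f), r_CV %.2f (SD %.2f) over %d folds\n",
              rel$r_d_mean, rel$r_d_sd, rel$r_cv_mean, rel$r_cv_sd,
              x$n_folds))
  invisible(x)
}

#' Derivation and cross-validated reliability of a selected scale
#'
#' Mean and sample SD, across cross-validation folds, of the derivation
#' correlation r_D (scale vs criterion on the training rows) and of the
#' cross-validated correlation r_CV (scale vs criterion on the held-out
#' rows) at the chosen scale size. Folds with an undefined correlation are
#' excluded.
#'
#' @param x A `biscuit_scale`, or a list with numeric `fold_r_d` and
#'   `fold_r_cv`.
#' @return List with `r_d_mean`, `r_d_sd`, `r_cv_mean`, `r_cv_sd`.
#' @export
summarize_reliability <- function(x) {
  d <- if (inherits(x, "biscuit_scale")) x$diagnostics else x
  rd <- d$fold_r_d[!is.na(d$fold_r_d)]
  rcv <- d$fold_r_cv[!is.na(d$fold_r_cv)]
  if (length(rd) == 0L && length(rcv) == 0L) {
    stop("no fold has a defined correlation", call. = FALSE)
  }
  list(
    r_d_mean = if (length(rd)) mean(rd) else NA_real_,
    r_d_sd = sample_sd(rd),
    r_cv_mean = if (length(rcv)) mean(rcv) else NA_real_,
    r_cv_sd = sample_sd(rcv)
  )
}

#' Write / read a selected scale as JSON
#'
#' @param scale A `biscuit_scale`.
#' @param path JSON file path.
#' @export
write_scale_json <- function(scale, path) {
  stopifnot(inherits(scale, "biscuit_scale"))
  obj <- unclass(scale)
  obj$diagnostics$ranking <- as.data.frame(obj$diagnostics$ranking)
  obj$diagnostics$k_table <- as.data.frame(obj$diagnostics$k_table)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_scale_json
#' @export
read_scale_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$diagnostics$ranking <- tibble::as_tibble(obj$diagnostics$ranking)
  obj$diagnostics$k_table <- tibble::as_tibble(obj$diagnostics$k_table)
  for (fld in c("keys", "r", "n_pairs", "mu", "sigma")) {
    obj[[fld]] <- as.numeric(obj[[fld]])
  }
  names(obj$mu) <- names(obj$sigma) <- obj$predictors
  structure(obj, class = "biscuit_scale")
}
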