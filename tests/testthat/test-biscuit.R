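test_that("pairwise-complete Pearson correlation matches hand computation", {
  expect_equal(pairwise_pearson(c(1, 2, 3, 4), c(0, 0, 1, 1)), 0.894427,
               tolerance = 1e-6)
  y <- c(0, 1, 0, 1, 1)
  expect_equal(pairwise_pearson(y, y), 1.0)
  expect_warning(r <- pairwise_pearson(rep(2, 5), y), "constant")
  expect_true(is.na(r))
  expect_warning(r2 <- pairwise_pearson(c(1, 2, NA, NA, NA), y), "complete")
  expect_true(is.na(r2))
  # missing values are dropped pairwise
  x <- c(1, 2, 3, 4, NA)
  expect_equal(suppressWarnings(pairwise_pearson(x, c(0, 0, 1, 1, 1))),
               0.894427, tolerance = 1e-6)
})

test_that("unit-weighted scoring is a prorated mean of keyed z scores", {
  sc <- structure(list(predictors = c("a", "b"), keys = c(1, -1),
                       mu = c(a = 0, b = 0), sigma = c(a = 1, b = 1)),
                  class = "biscuit_scale")
  one <- structure(list(predictors = "a", keys = 1,
                        mu = c(a = 0), sigma = c(a = 1)),
                   class = "biscuit_scale")
  expect_equal(unit_weighted_score(tibble::tibble(a = 1.2), one), 1.2)
  expect_equal(unit_weighted_score(tibble::tibble(a = 0.7, b = 0.7), sc), 0)
  # prorated over the observed keyed predictors
  expect_equal(unit_weighted_score(tibble::tibble(a = 2.0, b = NA), sc), 2.0)
  expect_true(is.na(unit_weighted_score(tibble::tibble(a = NA, b = NA), sc)))
  # standardization uses the stored derivation mean/SD
  sc2 <- structure(list(predictors = "a", keys = 1,
                        mu = c(a = 10), sigma = c(a = 5)),
                   class = "biscuit_scale")
  expect_equal(unit_weighted_score(tibble::tibble(a = 20), sc2), 2)
})

# Small complete-data matrix with a known planted signal.
make_selection_fixture <- function(n = 40, n_items = 6, seed = 42,
                                   signal = c("item_02", "item_05")) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)[sample.int(n)]
  m <- tibble::tibble(.rows = n)
  for (j in seq_len(n_items)) {
    nm <- sprintf("item_%02d", j)
    base <- stats::rnorm(n)
    if (nm %in% signal) base <- base + 2 * y
    m[[nm]] <- base
  }
  m$y_next <- y
  m
}

test_that("top-k selection equals a brute-force correlation sort", {
  for (seed in 1:10) {
    m <- make_selection_fixture(n = 30, n_items = 10, seed = seed)
    X <- as.matrix(m[, sprintf("item_%02d", 1:10)])
    for (k in c(1, 3, 7)) {
      sc <- suppressWarnings(
        biscuit_select(m, n_folds = 5, k_grid = k, seed = seed))
      expect_setequal(sc$predictors, top_k_brute(X, m$y_next, k))
      # and the ordering by |r| matches too
      expect_equal(sc$predictors, top_k_brute(X, m$y_next, k))
    }
  }
})

test_that("selection keys carry the sign of the derivation correlation", {
  m <- make_selection_fixture(seed = 7)
  m$item_03 <- -(2 * m$y_next + stats::rnorm(nrow(m), sd = 0.5))
  sc <- suppressWarnings(biscuit_select(m, n_folds = 5, k_grid = 3, seed = 1))
  expect_true("item_03" %in% sc$predictors)
  expect_equal(unname(sc$keys[sc$predictors == "item_03"]), -1)
  expect_equal(sign(sc$keys), sign(sc$r))
})

test_that("selection is invariant to sign flips and affine rescaling", {
  m <- make_selection_fixture(seed = 3)
  sc <- suppressWarnings(biscuit_select(m, n_folds = 5, seed = 9))
  s0 <- unit_weighted_score(m, sc)

  flipped <- m
  flipped$item_02 <- -flipped$item_02
  sc_f <- suppressWarnings(biscuit_select(flipped, n_folds = 5, seed = 9))
  expect_equal(sc_f$predictors, sc$predictors)
  expect_equal(unname(sc_f$keys[sc_f$predictors == "item_02"]),
               -unname(sc$keys[sc$predictors == "item_02"]))
  expect_equal(unit_weighted_score(flipped, sc_f), s0, tolerance = 1e-12)

  scaled <- m
  scaled$item_05 <- 3.7 * scaled$item_05 + 11
  sc_s <- suppressWarnings(biscuit_select(scaled, n_folds = 5, seed = 9))
  expect_equal(sc_s$predictors, sc$predictors)
  expect_equal(unit_weighted_score(scaled, sc_s), s0, tolerance = 1e-12)
})

test_that("fold assignment and selection are reproducible under a seed", {
  p <- generate_participant(truth_config(seed = 15L))
  m <- build_predictor_matrix(p)
  a <- suppressWarnings(biscuit_select(m, seed = 4))
  b <- suppressWarnings(biscuit_select(m, seed = 4))
  expect_identical(a, b)
  # a different seed reshuffles the folds
  folds_a <- emabiscuit:::assign_folds(m$y_next[!is.na(m$y_next)], 10,
                                       TRUE, seed = 4)
  folds_b <- emabiscuit:::assign_folds(m$y_next[!is.na(m$y_next)], 10,
                                       TRUE, seed = 5)
  expect_false(identical(folds_a, folds_b))
  # stratification puts positives in as many folds as possible
  y <- m$y_next[!is.na(m$y_next)]
  expect_equal(max(table(folds_a[y == 1])) - min(table(folds_a[y == 1])) <= 1,
               TRUE)
})

test_that("degenerate inputs are rejected or flagged", {
  m <- make_selection_fixture(seed = 5)
  m$y_next <- 0L
  expect_error(suppressWarnings(biscuit_select(m)), "distinct")
  m2 <- make_selection_fixture(seed = 5)
  m2$y_next <- c(1L, rep(0L, nrow(m2) - 1))
  expect_error(suppressWarnings(biscuit_select(m2)), "at least 2")
  expect_error(biscuit_select(make_selection_fixture(), k_grid = 0), ">= 1")
})

test_that("single-predictor degenerate grid returns that predictor", {
  set.seed(2)
  m <- tibble::tibble(item_01 = stats::rnorm(30))
  m$y_next <- as.integer(m$item_01 + stats::rnorm(30) > 0)
  sc <- suppressWarnings(biscuit_select(m, n_folds = 5, k_grid = 1, seed = 1))
  expect_equal(sc$predictors, "item_01")
  expect_equal(sc$k, 1)
  r_direct <- stats::cor(m$item_01, m$y_next)
  expect_equal(unname(sc$r), r_direct)
  # the fold-wise derivation correlations sit near the training |r|
  expect_lt(abs(mean(sc$diagnostics$fold_r_d) - abs(r_direct)), 0.15)
})

test_that("reliability summaries use fold means and sample SDs", {
  d <- list(fold_r_d = rep(0.4, 10), fold_r_cv = rep(0.4, 10))
  s <- summarize_reliability(d)
  expect_equal(s$r_d_mean, 0.40)
  expect_equal(s$r_d_sd, 0.00)
  two <- summarize_reliability(list(fold_r_d = c(0.3, 0.5),
                                    fold_r_cv = c(0.3, 0.5)))
  expect_equal(two$r_d_mean, 0.40)
  expect_equal(two$r_d_sd, 0.2 / sqrt(2))  # two-point sample SD
  # missing folds are excluded
  nine <- summarize_reliability(list(fold_r_d = c(rep(0.2, 9), NA),
                                     fold_r_cv = c(rep(0.1, 9), NA)))
  expect_equal(nine$r_d_mean, 0.2)
  expect_error(summarize_reliability(list(fold_r_d = rep(NA_real_, 3),
                                          fold_r_cv = rep(NA_real_, 3))),
               "no fold")
})

test_that("selected scales round-trip through JSON", {
  p <- generate_participant(truth_config(seed = 16L))
  m <- build_predictor_matrix(p)
  sc <- suppressWarnings(biscuit_select(m, seed = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_scale_json(sc, path)
  sc2 <- read_scale_json(path)
  expect_equal(sc2$predictors, sc$predictors)
  expect_equal(sc2$keys, unname(sc$keys))
  expect_equal(unname(sc2$mu), unname(sc$mu), tolerance = 1e-12)
  expect_equal(unit_weighted_score(m, sc2), unit_weighted_score(m, sc),
               tolerance = 1e-12)
})
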