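# Nested LOPO-CV elastic net: patient aggregation, penalty selection,
# pooled metrics, leakage guarantees, stability, bootstrap, and the
# legacy pre-screened comparator.

test_that("patient-level aggregation averages subcompartments", {
  obs <- tibble::tibble(
    patient_id = c("P1", "P2", "P2", "P3"),
    subcompartment = c("ET", "ET", "NET", "ET"),
    set_name = "SET_01",
    score = c(0, 1, 3, 4),
    n_zones = 1L, zones = "CT")
  rad <- tibble::tibble(
    patient_id = c("P1", "P2", "P2", "P3"),
    subcompartment = c("ET", "ET", "NET", "ET"),
    feat_0001 = c(1, 2, 4, 8))
  pt <- patient_level_table(obs, rad)
  expect_equal(nrow(pt), 3)
  # P2's feature = mean(2, 4); P1 (single row) passes through
  expect_equal(pt$feat_0001, c(1, 3, 8))
  # patient-level scores are z-scored: P1 0, P2 2, P3 4 -> (-1, 0, 1)*sd
  expect_equal(pt$SET_01, (c(0, 2, 4) - 2) / 2)
  # median variant coincides with mean for <= 2 rows per patient
  pt_med <- patient_level_table(obs, rad, aggregate = "median")
  expect_equal(pt_med$feat_0001, pt$feat_0001)
})

test_that("the cohort fixture collapses to 28 patient rows", {
  co <- small_cohort(seed = 23)
  scores <- ssgsea_scores(co$expression, co$gene_sets, samples = co$samples,
                          kernel_transform = FALSE)
  obs <- aggregate_to_subcompartments(scores, zone_map())
  pt <- patient_level_table(obs, co$radiomics)
  expect_equal(nrow(pt), 28)
  expect_true(all(co$gene_sets$set_name %in% names(pt)))
})

test_that("the top of the lambda path zeroes all slopes", {
  withr::with_seed(51, {
    X <- matrix(rnorm(40 * 4), 40,
                dimnames = list(NULL, paste0("f", 1:4)))
    y <- X[, 1] + rnorm(40, 0, 0.5)
  })
  # at lambda = max|<x_j, y>|/(n * alpha) (and above) all slopes are 0
  ys <- y - mean(y)
  Xs <- scale(X, scale = apply(X, 2, function(v)
    sqrt(mean((v - mean(v))^2))))
  lam_max <- max(abs(crossprod(Xs, ys))) / (nrow(X) * 0.5)
  fit <- elastic_net_fit(X, y, fixed_alpha = 0.5,
                         fixed_lambda = lam_max * 1.01)
  expect_equal(unname(fit$coefficients[paste0("f", 1:4)]), rep(0, 4))
  expect_equal(unname(fit$coefficients["(Intercept)"]), mean(y),
               tolerance = 1e-8)
})

test_that("lasso coefficients match the soft-threshold closed form on orthonormal designs", {
  # columns mean 0 and unit 1/n-variance, mutually orthogonal: the lasso
  # solution at penalty lambda is sign(z)(|z| - lambda)_+ with z = <x,y>/n
  withr::with_seed(52, {
    n <- 60
    x1 <- rnorm(n); x1 <- (x1 - mean(x1))
    x1 <- x1 / sqrt(mean(x1^2))
    x2 <- rnorm(n)
    x2 <- x2 - mean(x2) - x1 * mean(x1 * x2) / mean(x1^2)
    x2 <- x2 / sqrt(mean(x2^2))
    y <- 1.5 * x1 - 0.8 * x2 + rnorm(n, 0, 0.4)
  })
  soft <- function(z, l) sign(z) * pmax(abs(z) - l, 0)
  for (lam in c(0.05, 0.3, 0.9)) {
    fit <- elastic_net_fit(cbind(a = x1, b = x2), y,
                           fixed_alpha = 1, fixed_lambda = lam)
    closed <- c(soft(mean(x1 * y), lam), soft(mean(x2 * y), lam))
    expect_equal(unname(fit$coefficients[c("a", "b")]), closed,
                 tolerance = 1e-8)
  }
})

test_that("true predictors are recovered when the signal is strong", {
  hits <- purrr::map_lgl(1:5, function(s) {
    withr::with_seed(800 + s, {
      n <- 100
      X <- matrix(rnorm(n * 20), n,
                  dimnames = list(NULL, sprintf("f%02d", 1:20)))
      y <- 1.2 * X[, 3] - 0.9 * X[, 11] + rnorm(n, 0, 0.3)
    })
    fit <- elastic_net_fit(X, y, fast_en(seed = s))
    nz <- names(fit$coefficients)[fit$coefficients != 0]
    all(c("f03", "f11") %in% nz)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("R2cv is zero for the mean predictor and respects its definition", {
  y <- c(1, 2, 3, 4, 5, 6, 7, 9)
  m <- cv_metrics(y, rep(mean(y), 8))
  expect_equal(m$r2, 0)
  m2 <- cv_metrics(y, y)
  expect_equal(m2$r2, 1)
  expect_equal(m2$mae, 0)
  # affine invariance of R2cv
  a <- 3; b <- -2
  yhat <- y + rnorm(8, 0, 0.5)
  expect_equal(cv_metrics(a * y + b, a * yhat + b)$r2,
               cv_metrics(y, yhat)$r2, tolerance = 1e-12)
})

test_that("nested LOPO on a planted-signal table recovers signal and is deterministic", {
  pt <- make_ptable(n_patients = 24, n_features = 30, seed = 61,
                    signal = 1.3, n_signal = 3, noise = 0.4)
  cv1 <- nested_lopo(pt, "score", fast_en(seed = 7))
  cv2 <- nested_lopo(pt, "score", fast_en(seed = 7))
  expect_identical(glance(cv1), glance(cv2))
  expect_identical(cv1$folds$lambda, cv2$folds$lambda)
  expect_gt(cv1$r2_cv, 0.3)
  expect_true(all(sprintf("feat_%04d", 1:3) %in% cv1$stable_set))
  expect_equal(nrow(cv1$predictions), 24)
  expect_true(all(cv1$stability$fraction >= 0 & cv1$stability$fraction <= 1))
  expect_lte(cv1$r2_cv, 1)
})

test_that("perturbing the held-out patient never changes a nested fold", {
  pt <- make_ptable(n_patients = 16, n_features = 20, seed = 63,
                    signal = 1, n_signal = 2)
  cv1 <- nested_lopo(pt, "score", fast_en(seed = 3))
  pt2 <- pt
  pt2$score[1] <- 50  # wreck the held-out patient of fold 1
  cv2 <- nested_lopo(pt2, "score", fast_en(seed = 3))
  expect_identical(cv1$folds$selected[[1]], cv2$folds$selected[[1]])
  expect_equal(cv1$folds$alpha[1], cv2$folds$alpha[1])
  expect_equal(cv1$folds$lambda[1], cv2$folds$lambda[1])
  expect_equal(cv1$folds$prediction[1], cv2$folds$prediction[1])
})

test_that("null tables yield no-signal results with mean prediction", {
  pt <- make_ptable(n_patients = 14, n_features = 40, seed = 65, signal = 0)
  cv <- nested_lopo(pt, "score", fast_en(seed = 5))
  expect_lte(cv$r2_cv, 0.25)
  if (cv$status == "no signal") {
    # every prediction is a training mean
    expect_true(all(cv$folds$n_selected == 0))
  }
})

test_that("legacy pre-screening leaks: full-data selection, inflated apparent fit", {
  pt <- make_ptable(n_patients = 18, n_features = 60, seed = 67, signal = 0)
  leg <- legacy_prescreened_cv(pt, "score", fast_en(seed = 9), fdr_cut = 1)
  nest <- nested_lopo(pt, "score", fast_en(seed = 9), fdr_cut = 1)
  # same selection in every legacy fold
  expect_equal(length(unique(leg$folds$selected)), 1L)
  expect_gt(leg$apparent_r2, nest$r2_cv)
  # legacy mode picks up changes to any patient's score through the screen
  # while nested fold 1 does not (shown above); modes differ when the
  # full-data screen and a fold screen disagree
  expect_true(is.na(nest$apparent_r2))
})

test_that("bootstrap interval is degenerate for perfect predictions and reproducible", {
  pred <- tibble::tibble(y = rnorm(12, 0, 1))
  pred$yhat <- pred$y
  ci <- bootstrap_ci(pred, B = 300, seed = 1)
  expect_equal(c(ci$lower, ci$upper), c(1, 1))
  pt <- make_ptable(n_patients = 20, n_features = 10, seed = 69,
                    signal = 1, n_signal = 2)
  cv <- nested_lopo(pt, "score", fast_en(seed = 11))
  c1 <- bootstrap_ci(cv, B = 400, seed = 2)
  c2 <- bootstrap_ci(cv, B = 400, seed = 2)
  expect_identical(c1, c2)
  expect_lte(c1$lower, c1$upper)
  # null pathway: interval typically straddles zero
  ptn <- make_ptable(n_patients = 20, n_features = 10, seed = 71,
                     signal = 0)
  cvn <- nested_lopo(ptn, "score", fast_en(seed = 13), fdr_cut = 1)
  cin <- bootstrap_ci(cvn, B = 400, seed = 3)
  expect_lte(cin$lower, 0.2)
})
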