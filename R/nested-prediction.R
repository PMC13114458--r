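# Primary predictive framework: patient-level aggregation, elastic net
# with joint alpha/lambda selection (alpha by minimum inner-CV error,
# lambda by the one-standard-error rule), nested leave-one-patient-out
# cross-validation with in-fold screening, stability selection, bootstrap
# confidence intervals, and the legacy pre-screened comparator.

#' Elastic net configuration
#'
#' @param alpha_grid Mixing grid (default 0.1 to 1.0 in steps of 0.1; the
#'   pure-ridge limit is excluded so every fit is well-posed under
#'   collinearity).
#' @param n_lambda,lambda_min_ratio Penalty path length and min/max ratio.
#' @param lambda_rule `"one_se"` (default, the parsimony-favouring
#'   one-standard-error rule) or `"min"`.
#' @param inner_folds Inner cross-validation folds (default 5).
#' @param seed Seed for the deterministic inner-fold assignment.
#' @param fixed_alpha,fixed_lambda Optional fixed penalty: when both are
#'   given the inner CV is skipped and every fit uses this (alpha, lambda)
#'   pair. Used by fast large-replicate simulation designs where the
#'   penalty is part of the experimental condition rather than tuned.
#' @return An `elastic_net_config` list.
#' @export
elastic_net_config <- function(alpha_grid = seq(0.1, 1, by = 0.1),
                               n_lambda = 100, lambda_min_ratio = 1e-3,
                               lambda_rule = c("one_se", "min"),
                               inner_folds = 5, seed = 42,
                               fixed_alpha = NULL, fixed_lambda = NULL) {
  lambda_rule <- match.arg(lambda_rule)
  stopifnot(all(alpha_grid > 0 & alpha_grid <= 1), inner_folds >= 2)
  structure(list(alpha_grid = alpha_grid, n_lambda = n_lambda,
                 lambda_min_ratio = lambda_min_ratio,
                 lambda_rule = lambda_rule,
                 inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed),
                 fixed_alpha = fixed_alpha, fixed_lambda = fixed_lambda),
            class = "elastic_net_config")
}

# Deterministic inner-fold assignment: observations are blocked by the
# rank of the response and fold labels permuted within each block with a
# seeded RNG, stratifying the folds over the outcome range.
stratified_foldid <- function(y, k, seed) {
  n <- length(y)
  ord <- order(y, seq_len(n))
  fold <- integer(n)
  withr::with_seed(seed, {
    for (start in seq(1, n, by = k)) {
      block <- ord[start:min(start + k - 1, n)]
      fold[block] <- sample(k)[seq_along(block)]
    }
  })
  fold
}

#' Fit an elastic net with joint alpha/lambda selection
#'
#' The penalized objective is the usual
#' `(1/(2n)) * RSS + lambda * (alpha * L1 + (1 - alpha)/2 * L2)` with
#' features standardized on training statistics and coefficients returned
#' on the original scale (delegated to glmnet). For each alpha on the
#' grid, the mean inner-CV squared error curve over the lambda path is
#' computed with a deterministic, response-stratified fold assignment
#' shared across alphas; the chosen alpha minimizes the minimum mean CV
#' error (ties go to the smaller alpha), and lambda is then either the
#' minimizer (`"min"`) or the largest lambda whose mean CV error is within
#' one standard error of that minimum (`"one_se"`).
#'
#' @param X Numeric matrix (rows = training observations).
#' @param y Numeric response.
#' @param config An [elastic_net_config()].
#' @param fixed_alpha,fixed_lambda Optional: skip selection and fit at the
#'   given penalty (used for closed-form verification).
#' @return A list with `coefficients` (named, including `(Intercept)`),
#'   `alpha`, `lambda`, and `cv` (per-alpha summary tibble).
#' @export
elastic_net_fit <- function(X, y, config = elastic_net_config(),
                            fixed_alpha = NULL, fixed_lambda = NULL) {
  fixed_alpha <- fixed_alpha %||% config$fixed_alpha
  fixed_lambda <- fixed_lambda %||% config$fixed_lambda
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  keep_names <- colnames(X)
  if (sd(y) == 0) {
    co <- setNames(c(mean(y), rep(0, ncol(X))),
                   c("(Intercept)", keep_names))
    return(list(coefficients = co, alpha = NA_real_, lambda = Inf,
                cv = tibble()))
  }
  # glmnet needs >= 2 columns; pad single-feature designs with a null column
  padded <- FALSE
  if (ncol(X) == 1) {
    X <- cbind(X, `.null.` = 0)
    padded <- TRUE
  }
  if (!is.null(fixed_alpha) && !is.null(fixed_lambda)) {
    fit <- glmnet::glmnet(X, y, alpha = fixed_alpha, lambda = fixed_lambda,
                          standardize = TRUE, thresh = 1e-12)
    co <- as.numeric(coef(fit))
    names(co) <- rownames(coef(fit))
    if (padded) co <- co[names(co) != ".null."]
    return(list(coefficients = co, alpha = fixed_alpha,
                lambda = fixed_lambda, cv = tibble()))
  }
  if (nrow(X) < config$inner_folds + 1) {
    abort("Need at least inner_folds + 1 training rows.")
  }
  foldid <- stratified_foldid(y, config$inner_folds, config$seed)
  k <- config$inner_folds
  per_alpha <- purrr::map(config$alpha_grid, function(a) {
    # lambda path from the full training fit (largest lambda zeroes all
    # coefficients), then the inner-CV error curve over held-out folds
    path_fit <- glmnet::glmnet(X, y, alpha = a, nlambda = config$n_lambda,
                               lambda.min.ratio = config$lambda_min_ratio,
                               standardize = TRUE, thresh = 1e-8)
    lambda <- path_fit$lambda
    fold_mse <- matrix(NA_real_, k, length(lambda))
    for (f in seq_len(k)) {
      in_f <- foldid == f
      fit_f <- glmnet::glmnet(X[!in_f, , drop = FALSE], y[!in_f],
                              alpha = a, lambda = lambda,
                              standardize = TRUE, thresh = 1e-8)
      pred <- predict(fit_f, X[in_f, , drop = FALSE])
      fold_mse[f, seq_len(ncol(pred))] <-
        colMeans((y[in_f] - pred)^2)
    }
    cvm <- colMeans(fold_mse)
    cvsd <- apply(fold_mse, 2, sd) / sqrt(k)
    ok <- is.finite(cvm)
    i_min <- which(ok & cvm <= min(cvm[ok]))[1]   # largest such lambda
    i_1se <- which(ok & cvm <= cvm[i_min] + cvsd[i_min])[1]
    list(alpha = a, fit = path_fit, min_cvm = cvm[i_min],
         lambda_min = lambda[i_min], lambda_1se = lambda[i_1se])
  })
  min_cvms <- vapply(per_alpha, `[[`, numeric(1), "min_cvm")
  best <- per_alpha[[which.min(min_cvms)]]  # ties -> smaller alpha
  lambda <- if (config$lambda_rule == "one_se") best$lambda_1se
  else best$lambda_min
  co <- as.numeric(coef(best$fit, s = lambda, exact = FALSE))
  names(co) <- rownames(coef(best$fit, s = lambda))
  if (padded) co <- co[names(co) != ".null."]
  list(coefficients = co, alpha = best$alpha, lambda = lambda,
       cv = tibble(alpha = config$alpha_grid, min_cvm = min_cvms))
}

predict_en <- function(coefficients, X) {
  X <- as.matrix(X)
  b <- coefficients[setdiff(names(coefficients), "(Intercept)")]
  as.numeric(coefficients[["(Intercept)"]] +
               X[, names(b), drop = FALSE] %*% b)
}

#' Collapse observations to one row per patient
#'
#' Pathway scores and radiomic features are aggregated (mean by default,
#' median for the S3 sensitivity variant) across each patient's available
#' subcompartments, yielding independent patient-level observations for
#' the predictive analysis.
#'
#' @param obs Observation table (all sets).
#' @param radiomics Radiomic table.
#' @param aggregate `"mean"` or `"median"`.
#' @return A tibble with one row per patient: `patient_id`, one column per
#'   gene set (globally z-scored patient-level score), and the feature
#'   columns.
#' @export
patient_level_table <- function(obs, radiomics,
                                aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "mean") mean else median
  scores <- obs |>
    summarise(score = agg(.data$score), .by = c("patient_id", "set_name")) |>
    mutate(score = zscore(.data$score), .by = "set_name") |>
    tidyr::pivot_wider(names_from = "set_name", values_from = "score")
  feats <- feature_columns(radiomics)
  fx <- radiomics |>
    summarise(across(dplyr::all_of(feats), agg), .by = "patient_id")
  inner_join(scores, fx, by = "patient_id")
}

#' Pooled cross-validation metrics
#'
#' `r2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)` (pooled over all
#' held-out predictions, with the overall observed mean in the
#' denominator), mean absolute error, and Spearman correlation between
#' observed and predicted.
#'
#' @param y Observed values.
#' @param yhat Held-out predictions.
#' @return A list with `r2`, `mae`, `spearman_rho`.
#' @export
cv_metrics <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  sst <- sum((y - mean(y))^2)
  list(r2 = 1 - sum((y - yhat)^2) / sst,
       mae = mean(abs(y - yhat)),
       spearman_rho = if (sd(yhat) == 0) NA_real_ else
         cor(rank(y), rank(yhat)))
}

# Fold loop shared by the public nested CV and the permutation reruns:
# plain vectors in, plain lists out (the permutation null only needs the
# pooled R2, so no result tables are assembled here).
lopo_core <- function(X_all, y_all, patients, en_config, fdr_cut, cap,
                      prescreen = NULL) {
  lapply(seq_along(patients), function(i) {
    y_tr <- y_all[-i]
    # in-fold screening: the held-out patient never enters the statistics
    sel <- prescreen %||%
      screen_select(X_all[-i, , drop = FALSE], y_tr, fdr_cut, cap)
    if (!length(sel)) {
      return(list(patient_id = patients[i], selected = character(0),
                  alpha = NA_real_, lambda = NA_real_,
                  prediction = mean(y_tr), n_train = length(y_tr)))
    }
    cfg <- en_config
    cfg$seed <- derive_seed(en_config$seed, "fold", patients[i])
    fit <- elastic_net_fit(X_all[-i, sel, drop = FALSE], y_tr, cfg)
    pred <- predict_en(fit$coefficients, X_all[i, sel, drop = FALSE])
    list(patient_id = patients[i], selected = sel, alpha = fit$alpha,
         lambda = fit$lambda, prediction = pred, n_train = length(y_tr))
  })
}

lopo_r2 <- function(X_all, y_all, patients, en_config, fdr_cut, cap) {
  folds <- lopo_core(X_all, y_all, patients, en_config, fdr_cut, cap)
  preds <- vapply(folds, `[[`, numeric(1), "prediction")
  cv_metrics(y_all, preds)$r2
}

run_lopo <- function(ptable, set_name, feats, en_config, fdr_cut, cap,
                     prescreen = NULL) {
  patients <- ptable$patient_id
  y_all <- ptable[[set_name]]
  X_all <- as.matrix(ptable[feats])
  rownames(X_all) <- NULL
  folds <- lopo_core(X_all, y_all, patients, en_config, fdr_cut, cap,
                     prescreen = prescreen)
  preds <- vapply(folds, `[[`, numeric(1), "prediction")
  met <- cv_metrics(y_all, preds)
  sel_list <- purrr::map(folds, "selected")
  stability <- tibble(feature = feats) |>
    mutate(fraction = vapply(.data$feature, function(f)
      mean(vapply(sel_list, function(s) f %in% s, logical(1))), numeric(1))) |>
    filter(.data$fraction > 0) |>
    arrange(desc(.data$fraction), .data$feature)
  list(
    folds = tibble(
      patient_id = patients,
      selected = sel_list,
      n_selected = lengths(sel_list),
      alpha = vapply(folds, `[[`, numeric(1), "alpha"),
      lambda = vapply(folds, `[[`, numeric(1), "lambda"),
      prediction = preds, n_train = vapply(folds, `[[`, numeric(1), "n_train")
    ),
    predictions = tibble(patient_id = patients, y = y_all, yhat = preds),
    metrics = met, stability = stability
  )
}

#' Nested leave-one-patient-out cross-validated elastic net
#'
#' For each fold, one patient is held out; the univariate Spearman screen
#' (FDR < `fdr_cut`, top `cap` by raw p) runs on the training patients
#' only; an elastic net is fitted on the selected features and the
#' held-out patient is predicted. Folds with an empty selection predict
#' the training mean, which keeps the pooled metric defined and naturally
#' penalizes no-signal pathways. Stability is the per-feature fraction of
#' folds selecting it; features above 0.5 form the stable set. If every
#' fold had an empty selection the result carries status `"no signal"`.
#'
#' @param ptable Patient-level table from [patient_level_table()].
#' @param set_name Gene set (response column of `ptable`).
#' @param en_config An [elastic_net_config()].
#' @param fdr_cut,cap In-fold screening thresholds (defaults 0.10, 5).
#' @param feature_cols Candidate feature columns (default: all `feat_*`
#'   style columns, i.e. everything that is not a gene set or id).
#' @return An `rg_nestedcv` object: metrics (`r2_cv`, `mae`,
#'   `spearman_rho`), per-fold records, held-out predictions, stability
#'   table and stable set, and `status` (`"ok"` or `"no signal"`).
#' @export
nested_lopo <- function(ptable, set_name, en_config = elastic_net_config(),
                        fdr_cut = 0.10, cap = 5, feature_cols = NULL) {
  if (nrow(ptable) < 8) abort("Nested LOPO-CV needs >= 8 patients.")
  feats <- feature_cols %||% grep("^feat_", names(ptable), value = TRUE)
  res <- run_lopo(ptable, set_name, feats, en_config, fdr_cut, cap)
  status <- if (all(res$folds$n_selected == 0)) "no signal" else "ok"
  structure(list(
    set_name = set_name, r2_cv = res$metrics$r2, mae = res$metrics$mae,
    spearman_rho = res$metrics$spearman_rho, folds = res$folds,
    predictions = res$predictions, stability = res$stability,
    stable_set = res$stability$feature[res$stability$fraction > 0.5],
    status = status, mode = "nested", apparent_r2 = NA_real_,
    n_patients = nrow(ptable), config = en_config,
    fdr_cut = fdr_cut, cap = cap
  ), class = "rg_nestedcv")
}

#' Legacy pre-screened comparator
#'
#' Identical to [nested_lopo()] except that the univariate screen runs
#' once on all patients before the cross-validation loop — the selection
#' leaks the held-out patients into every fold. Also records the apparent
#' (in-sample) R2 of the model refitted on the full data, the quantity
#' the leakage inflates.
#'
#' @inheritParams nested_lopo
#' @return An `rg_nestedcv` with `mode = "legacy"` and `apparent_r2`.
#' @export
legacy_prescreened_cv <- function(ptable, set_name,
                                  en_config = elastic_net_config(),
                                  fdr_cut = 0.10, cap = 5,
                                  feature_cols = NULL) {
  if (nrow(ptable) < 8) abort("Needs >= 8 patients.")
  feats <- feature_cols %||% grep("^feat_", names(ptable), value = TRUE)
  scr <- univariate_screen(
    ptable[c("patient_id", feats)],
    ptable |> select("patient_id", score = dplyr::all_of(set_name)),
    mode = "patient_level", fdr_cut = fdr_cut, cap = cap)
  res <- run_lopo(ptable, set_name, feats, en_config, fdr_cut, cap,
                  prescreen = scr$selected)
  apparent <- NA_real_
  y <- ptable[[set_name]]
  if (length(scr$selected)) {
    cfg <- en_config
    cfg$seed <- derive_seed(en_config$seed, "apparent")
    fit <- elastic_net_fit(as.matrix(ptable[scr$selected]), y, cfg)
    yhat <- predict_en(fit$coefficients, ptable[scr$selected])
    apparent <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  } else {
    apparent <- 0
  }
  status <- if (!length(scr$selected)) "no signal" else "ok"
  structure(list(
    set_name = set_name, r2_cv = res$metrics$r2, mae = res$metrics$mae,
    spearman_rho = res$metrics$spearman_rho, folds = res$folds,
    predictions = res$predictions, stability = res$stability,
    stable_set = res$stability$feature[res$stability$fraction > 0.5],
    status = status, mode = "legacy", apparent_r2 = apparent,
    n_patients = nrow(ptable), config = en_config,
    fdr_cut = fdr_cut, cap = cap
  ), class = "rg_nestedcv")
}

#' @export
print.rg_nestedcv <- function(x, ...) {
  cat(sprintf(
    "<rg_nestedcv:%s> %s: R2cv=%.3f MAE=%.3f rho=%.3f stable=%d [%s]\n",
    x$mode, x$set_name, x$r2_cv, x$mae, x$spearman_rho,
    length(x$stable_set), x$status))
  invisible(x)
}

#' Bootstrap confidence interval for the cross-validated R2
#'
#' Nonparametric percentile interval: the (y, yhat) pairs are resampled
#' with replacement B times and R2 recomputed with the resample's own
#' mean; the interval conditions on the fitted predictions and captures
#' metric sampling variability only. Degenerate resamples (zero variance
#' in y) are redrawn and counted.
#'
#' @param x An `rg_nestedcv`, or a tibble/list with `y` and `yhat`.
#' @param B Number of bootstrap resamples (>= 200; default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Seed.
#' @return A list with `lower`, `upper`, `level`, `B`, `n_redrawn`.
#' @export
bootstrap_ci <- function(x, B = 1000, level = 0.95, seed = 42) {
  if (inherits(x, "rg_nestedcv")) x <- x$predictions
  y <- x$y; yhat <- x$yhat
  stopifnot(length(y) >= 8, B >= 200)
  n <- length(y)
  redrawn <- 0
  stats <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      repeat {
        i <- sample(n, replace = TRUE)
        if (sd(y[i]) > 0) break
        redrawn <<- redrawn + 1
      }
      1 - sum((y[i] - yhat[i])^2) / sum((y[i] - mean(y[i]))^2)
    }, numeric(1))
  })
  a <- (1 - level) / 2
  q <- unname(quantile(stats, c(a, 1 - a), type = 7))
  list(lower = q[1], upper = q[2], level = level, B = B,
       n_redrawn = redrawn)
}
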