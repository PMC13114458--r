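# Per-pathway linear mixed-effects association: z-scoring, full/null model
# pairs with patient random intercepts, likelihood-ratio omnibus test,
# Nakagawa-Schielzeth R2 decomposition, ICC, Holm-corrected coefficients,
# covariate ladder, and the campaign over all gene sets with padded FDR.

#' z-score a numeric vector, optionally within groups
#'
#' Mean 0 and SD 1 (denominator n - 1) within each group.
#'
#' @param x Numeric vector.
#' @param group Optional grouping vector (`NULL` = global).
#' @return The standardized vector; groups with zero variance return `NA`
#'   with a warning (callers drop such features).
#' @export
zscore <- function(x, group = NULL) {
  if (is.null(group)) group <- rep(1L, length(x))
  out <- rep(NA_real_, length(x))
  for (g in unique(group)) {
    i <- which(group == g)
    s <- sd(x[i])
    if (!is.finite(s) || s == 0) {
      warn("Zero variance within a standardization group; values set to NA.")
      next
    }
    out[i] <- (x[i] - mean(x[i])) / s
  }
  out
}

#' Build the analysis table for one pathway
#'
#' Joins the observation rows of one gene set with the selected radiomic
#' features and optional covariates; the pathway score is globally
#' z-scored (`z_pathway`), the features are z-scored within
#' subcompartment by default (`standardization = "global"` is the S7
#' sensitivity variant). Features that are constant within a
#' standardization group are dropped with a warning.
#'
#' @param obs Observation table from [aggregate_to_subcompartments()].
#' @param radiomics Radiomic table.
#' @param features Character vector of feature ids (e.g. the `selected`
#'   element of a [univariate_screen()] result).
#' @param set_name Gene set.
#' @param covariates Optional covariate tibble (`patient_id`, `age`,
#'   `mgmt_methylated`, `subtype`).
#' @param standardization `"within_subcompartment"` (default) or
#'   `"global"`.
#' @return A tibble with `patient_id`, `subcompartment`, `z_pathway`, the
#'   z-scored features (original names), and covariates when supplied. The
#'   retained feature names are stored in the `features` attribute.
#' @export
build_analysis_table <- function(obs, radiomics, features, set_name,
                                 covariates = NULL,
                                 standardization = c("within_subcompartment",
                                                     "global")) {
  standardization <- match.arg(standardization)
  d <- obs |>
    filter(.data$set_name == !!set_name) |>
    select("patient_id", "subcompartment", "score") |>
    inner_join(radiomics[c("patient_id", "subcompartment", features)],
               by = c("patient_id", "subcompartment")) |>
    mutate(z_pathway = zscore(.data$score), score = NULL)
  grp <- if (standardization == "within_subcompartment")
    d$subcompartment else NULL
  kept <- character(0)
  for (f in features) {
    z <- withCallingHandlers(zscore(d[[f]], grp),
                             warning = function(w) invokeRestart("muffleWarning"))
    if (anyNA(z)) {
      warn(sprintf("Feature %s constant within a group; dropped.", f))
      d[[f]] <- NULL
    } else {
      d[[f]] <- z
      kept <- c(kept, f)
    }
  }
  if (!is.null(covariates)) {
    d <- left_join(d, covariates, by = "patient_id")
  }
  d$subcompartment <- factor(d$subcompartment, levels = c("ET", "NET", "ED"))
  d$patient_id <- factor(d$patient_id)
  attr(d, "features") <- kept
  d
}

nakagawa_components <- function(model) {
  X <- lme4::getME(model, "X")
  fixed_pred <- as.numeric(X %*% lme4::fixef(model))
  n <- length(fixed_pred)
  var_f <- sum((fixed_pred - mean(fixed_pred))^2) / n  # population variance
  vc <- lme4::VarCorr(model)
  var_u <- as.numeric(vc$patient_id[1, 1])
  var_e <- stats::sigma(model)^2
  list(var_f = var_f, var_u = var_u, var_e = var_e,
       r2m = var_f / (var_f + var_u + var_e),
       r2c = (var_f + var_u) / (var_f + var_u + var_e))
}

fit_ml <- function(formula, data) {
  msgs <- character(0)
  fit <- withCallingHandlers(
    lme4::lmer(formula, data = data, REML = FALSE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular =
                                             lme4::.makeCC("ignore", tol = 1e-4))),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  list(fit = fit, converged = !any(grepl("failed to converge", msgs)))
}

#' Fit the full/null mixed-model pair for one pathway
#'
#' Full model: `z_pathway ~ features + covariates + subcompartment +
#' (1 | patient_id)`; null model drops the radiomic features (covariates,
#' when present, stay in both models so the likelihood-ratio test isolates
#' the radiomic contribution). Both models are fitted by maximum
#' likelihood. The omnibus statistic is `chi2 = max(0, 2 (llf - lln))`
#' with `df = k` features; marginal/conditional R2 follow the
#' Nakagawa-Schielzeth variance decomposition (fixed-effect predictor
#' variance over fixed + intercept + residual variance), and the ICC is
#' computed from the null model. Per-coefficient p-values use the Wald
#' normal reference and are Holm-corrected across the k radiomic terms;
#' confidence intervals are Wald intervals.
#'
#' @param data Analysis table from [build_analysis_table()].
#' @param features Feature columns to use (default: the table's
#'   `features` attribute).
#' @param covariates Covariate column names included in both models.
#' @return An `rg_lmm` object (list with `chi2`, `df`, `lrt_p`,
#'   `r2m_null`, `r2m_full`, `delta_r2m`, `r2c`, `icc`, `coefficients`
#'   tibble, `converged`, `n_obs`, `n_patients`, and the fitted models).
#' @export
fit_lmm_pair <- function(data, features = attr(data, "features"),
                         covariates = character(0)) {
  if (!length(features)) abort("Need >= 1 radiomic feature; use k >= 1.")
  tab <- table(data$patient_id)
  if (sum(tab >= 2) < 2) {
    warn("Fewer than 2 patients with repeated observations; random intercept weakly identified.")
  }
  if (sd(data$z_pathway) == 0) {
    # degenerate response: both models are flat; no radiomic evidence
    coefs <- tibble(term = features, estimate = 0, std_error = NA_real_,
                    statistic = NA_real_, p_value = 1, holm_p = 1,
                    conf_low = NA_real_, conf_high = NA_real_)
    return(structure(list(
      chi2 = 0, df = length(features), lrt_p = 1,
      r2m_null = 0, r2m_full = 0, delta_r2m = 0, r2c = 0, icc = NA_real_,
      coefficients = coefs, converged = TRUE, n_obs = nrow(data),
      n_patients = length(unique(data$patient_id)), features = features,
      covariates = covariates, model_full = NULL, model_null = NULL
    ), class = "rg_lmm"))
  }
  rhs_common <- c(covariates, "subcompartment")
  f_full <- as.formula(paste("z_pathway ~",
                             paste(c(sprintf("`%s`", features), rhs_common),
                                   collapse = " + "), "+ (1 | patient_id)"))
  f_null <- as.formula(paste("z_pathway ~", paste(rhs_common, collapse = " + "),
                             "+ (1 | patient_id)"))
  full <- fit_ml(f_full, data)
  null <- fit_ml(f_null, data)
  chi2 <- max(0, 2 * (as.numeric(logLik(full$fit)) -
                        as.numeric(logLik(null$fit))))
  k <- length(features)
  lrt_p <- pchisq(chi2, df = k, lower.tail = FALSE)
  comp_full <- nakagawa_components(full$fit)
  comp_null <- nakagawa_components(null$fit)
  icc <- comp_null$var_u / (comp_null$var_u + comp_null$var_e)

  ct <- summary(full$fit)$coefficients
  rows <- match(sprintf("`%s`", features), rownames(ct))
  rows[is.na(rows)] <- match(features, rownames(ct))[is.na(rows)]
  est <- ct[rows, "Estimate"]; se <- ct[rows, "Std. Error"]
  zstat <- est / se
  p <- 2 * pnorm(-abs(zstat))
  coefs <- tibble(
    term = features, estimate = unname(est), std_error = unname(se),
    statistic = unname(zstat), p_value = unname(p),
    holm_p = p.adjust(p, method = "holm"),
    conf_low = unname(est - qnorm(0.975) * se),
    conf_high = unname(est + qnorm(0.975) * se)
  )

  structure(list(
    chi2 = chi2, df = k, lrt_p = lrt_p,
    r2m_null = comp_null$r2m, r2m_full = comp_full$r2m,
    delta_r2m = comp_full$r2m - comp_null$r2m, r2c = comp_full$r2c,
    icc = icc, coefficients = coefs,
    converged = full$converged && null$converged,
    n_obs = nrow(data), n_patients = length(unique(data$patient_id)),
    features = features, covariates = covariates,
    model_full = full$fit, model_null = null$fit
  ), class = "rg_lmm")
}

#' @export
print.rg_lmm <- function(x, ...) {
  cat(sprintf(
    "<rg_lmm> k=%d chi2=%.2f (df=%d) p=%.4g | R2m %0.3f -> %0.3f (d=%+0.3f) R2c=%.3f ICC=%.3f%s\n",
    x$df, x$chi2, x$df, x$lrt_p, x$r2m_null, x$r2m_full, x$delta_r2m,
    x$r2c, x$icc, if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Residual and influence diagnostics for a fitted pathway model
#'
#' Shapiro-Wilk normality of conditional residuals and exact
#' leave-one-observation-out influence (refitting the full model without
#' each row and recording the largest standardized change in the radiomic
#' coefficients). Reported, never asserted.
#'
#' @param fit An `rg_lmm`.
#' @param data The analysis table it was fitted on.
#' @return A list with `shapiro_p` and an `influence` tibble.
#' @export
lmm_diagnostics <- function(fit, data) {
  res <- stats::residuals(fit$model_full)
  shapiro_p <- if (length(res) >= 3 && length(res) <= 5000)
    stats::shapiro.test(res)$p.value else NA_real_
  base <- fit$coefficients$estimate
  se <- fit$coefficients$std_error
  infl <- purrr::map_dfr(seq_len(nrow(data)), function(i) {
    ref <- try(fit_lmm_pair(data[-i, ], features = fit$features,
                            covariates = fit$covariates), silent = TRUE)
    if (inherits(ref, "try-error")) {
      return(tibble(row = i, max_std_change = NA_real_))
    }
    tibble(row = i,
           max_std_change = max(abs(ref$coefficients$estimate - base) / se))
  })
  list(shapiro_p = shapiro_p, influence = infl)
}

#' Run the mixed-model campaign over a gene-set collection
#'
#' For each set: a full-data per-subcompartment univariate screen; sets
#' with an empty selection receive p = 1.0 and k = 0; the rest are fitted
#' with [fit_lmm_pair()]. FDR is the conservative padded
#' Benjamini-Hochberg across `n_total` pathways (untested sets enter at
#' p = 1.0). Non-converged fits are reported with p set to 1.0 and flagged.
#'
#' @param obs Observation table.
#' @param radiomics Reduced radiomic table.
#' @param sets Character vector of set names (default: all in `obs`).
#' @param n_total Total pathway family size for the padded FDR (default:
#'   number of sets).
#' @param fdr_cut,cap Screening thresholds (defaults 0.10 and 5).
#' @param standardization Feature standardization mode.
#' @param categories Optional named vector `set_name -> category` carried
#'   into the report.
#' @return An `rg_lmm_campaign`: list with `results` (tibble shaped like a
#'   per-pathway association table: set, category, k, r2m_null, r2m_full,
#'   delta_r2m, r2c, lrt_p, fdr), `fits`, and `screens`.
#' @export
run_lmm_campaign <- function(obs, radiomics, sets = NULL, n_total = NULL,
                             fdr_cut = 0.10, cap = 5,
                             standardization = "within_subcompartment",
                             categories = NULL) {
  sets <- sets %||% unique(obs$set_name)
  n_total <- n_total %||% length(sets)
  screens <- list(); fits <- list()
  rows <- purrr::map_dfr(sets, function(s) {
    scr <- univariate_screen(radiomics, obs, set_name = s,
                             mode = "per_subcompartment",
                             fdr_cut = fdr_cut, cap = cap)
    screens[[s]] <<- scr
    if (!length(scr$selected)) {
      return(tibble(set_name = s, k = 0L, r2m_null = NA_real_,
                    r2m_full = NA_real_, delta_r2m = NA_real_,
                    r2c = NA_real_, lrt_p = 1.0, converged = TRUE))
    }
    d <- build_analysis_table(obs, radiomics, scr$selected, s,
                              standardization = standardization)
    fit <- fit_lmm_pair(d)
    fits[[s]] <<- fit
    tibble(set_name = s, k = fit$df, r2m_null = fit$r2m_null,
           r2m_full = fit$r2m_full, delta_r2m = fit$delta_r2m,
           r2c = fit$r2c,
           lrt_p = if (fit$converged) fit$lrt_p else 1.0,
           converged = fit$converged)
  })
  adj <- adjust_bh(rows$lrt_p, labels = rows$set_name, m = n_total)
  rows$fdr <- adj$adjusted[match(rows$set_name, adj$label)]
  if (!is.null(categories)) {
    rows <- rows |> mutate(category = unname(categories[.data$set_name]),
                           .after = "set_name")
  }
  rows <- rows |> arrange(.data$fdr, .data$lrt_p)
  structure(list(results = rows, fits = fits, screens = screens,
                 n_total = n_total),
            class = "rg_lmm_campaign")
}

#' @export
print.rg_lmm_campaign <- function(x, ...) {
  cat(sprintf("<rg_lmm_campaign> %d sets (FDR family m=%d), %d with features\n",
              nrow(x$results), x$n_total, sum(x$results$k > 0)))
  print(x$results, n = 12)
  invisible(x)
}

#' Covariate-adjustment ladder
#'
#' Refits the full/null pair with progressively richer covariate sets;
#' the covariates enter both models, so the likelihood-ratio test always
#' isolates the radiomic contribution.
#'
#' @param data Analysis table including covariate columns (see
#'   [build_analysis_table()] with `covariates`).
#' @param features Radiomic feature columns.
#' @param models Named list of covariate vectors; default the A-D ladder
#'   (none; age; age + MGMT; age + MGMT + subtype).
#' @return A tibble keyed by `model` with the fit summaries, and the fits
#'   in the `fits` attribute. Rank-deficient subtype models at small n are
#'   flagged via `converged`.
#' @export
covariate_ladder <- function(data, features = attr(data, "features"),
                             models = list(A = character(0),
                                           B = "age",
                                           C = c("age", "mgmt_methylated"),
                                           D = c("age", "mgmt_methylated",
                                                 "subtype"))) {
  fits <- list()
  out <- purrr::imap_dfr(models, function(covs, nm) {
    missing <- setdiff(covs, names(data))
    if (length(missing)) {
      abort(sprintf("Covariate(s) missing from data: %s",
                    paste(missing, collapse = ", ")))
    }
    fit <- fit_lmm_pair(data, features = features, covariates = covs)
    fits[[nm]] <<- fit
    tibble(model = nm, covariates = paste(covs, collapse = "+"),
           k = fit$df, chi2 = fit$chi2, lrt_p = fit$lrt_p,
           r2m_full = fit$r2m_full, delta_r2m = fit$delta_r2m,
           r2c = fit$r2c, converged = fit$converged)
  })
  attr(out, "fits") <- fits
  out
}
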