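# broom-style tidiers for the fitted result objects.

#' Tidy a mixed-model pathway fit
#'
#' @param x An `rg_lmm`.
#' @param ... Unused.
#' @return One row per radiomic coefficient: `term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`, `holm_p`, `conf_low`,
#'   `conf_high`.
#' @exportS3Method generics::tidy
tidy.rg_lmm <- function(x, ...) x$coefficients

#' @rdname tidy.rg_lmm
#' @return For `glance()`: a one-row model summary.
#' @exportS3Method generics::glance
glance.rg_lmm <- function(x, ...) {
  tibble(k = x$df, chi2 = x$chi2, lrt_p = x$lrt_p, r2m_null = x$r2m_null,
         r2m_full = x$r2m_full, delta_r2m = x$delta_r2m, r2c = x$r2c,
         icc = x$icc, converged = x$converged, n_obs = x$n_obs,
         n_patients = x$n_patients)
}

#' Tidy a nested cross-validation result
#'
#' @param x An `rg_nestedcv`.
#' @param ... Unused.
#' @return `tidy()`: the stability table (`feature`, `fraction`,
#'   `stable`); `glance()`: a one-row metric summary.
#' @exportS3Method generics::tidy
tidy.rg_nestedcv <- function(x, ...) {
  x$stability |> mutate(stable = .data$fraction > 0.5)
}

#' @rdname tidy.rg_nestedcv
#' @exportS3Method generics::glance
glance.rg_nestedcv <- function(x, ...) {
  tibble(set_name = x$set_name, mode = x$mode, r2_cv = x$r2_cv,
         mae = x$mae, spearman_rho = x$spearman_rho,
         n_stable = length(x$stable_set), status = x$status,
         apparent_r2 = x$apparent_r2, n_patients = x$n_patients)
}

#' Tidy a permutation test
#'
#' @param x An `rg_perm`.
#' @param ... Unused.
#' @return `tidy()`: the null distribution in long form; `glance()`: one
#'   row per statistic with observed value and permutation p.
#' @exportS3Method generics::tidy
tidy.rg_perm <- function(x, ...) {
  x$null |> tidyr::pivot_longer(dplyr::everything(),
                                names_to = "statistic",
                                values_to = "value")
}

#' @rdname tidy.rg_perm
#' @exportS3Method generics::glance
glance.rg_perm <- function(x, ...) {
  tibble(framework = x$framework, statistic = names(x$observed),
         observed = unlist(x$observed), p = unlist(x$p),
         n_perm = x$n_perm)
}

#' Tidy a univariate screen
#'
#' @param x An `rg_screen`.
#' @param ... Unused.
#' @return The per-feature summary (min FDR, min raw p, eligibility,
#'   selection).
#' @exportS3Method generics::tidy
tidy.rg_screen <- function(x, ...) x$summary
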