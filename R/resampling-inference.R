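# Permutation frameworks (patient-level for the mixed model; fully nested
# for the cross-validated elastic net) and the multiplicity corrections
# (standard BH, conservative padded BH, restricted-set BH, Holm).

#' Benjamini-Hochberg adjustment with optional conservative padding
#'
#' Standard step-up BH; when `m` exceeds the number of supplied p-values,
#' the family is padded with `m - length(p)` placeholder values of 1.0
#' for untested hypotheses before adjusting — the conservative policy
#' that inflates the denominator of every tested hypothesis. The
#' placeholder entries are reported separately (`padded = TRUE`).
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @param labels Optional labels.
#' @param m Family size; default `length(p)` (no padding). Must be >=
#'   `length(p)`.
#' @return A tibble (`label`, `p`, `adjusted`, `padded`) with the family
#'   size in the `m` attribute; adjusted values are capped at 1 and are
#'   monotone in the raw-p ordering.
#' @examples
#' adjust_bh(c(0.006, 0.008, 0.013))$adjusted          # 0.012 0.012 0.013
#' adjust_bh(c(0.006, 0.008, 0.013), m = 24)$adjusted  # 0.096 0.096 0.104
#' @export
adjust_bh <- function(p, labels = NULL, m = NULL) {
  assert_prob(p, "p")
  m <- m %||% length(p)
  if (m < length(p)) abort("`m` must be >= length(p).")
  labels <- labels %||% as.character(seq_along(p))
  n_real <- length(p)
  n_pad <- m - n_real
  p_all <- c(p, rep(1.0, n_pad))
  adj <- p.adjust(p_all, method = "BH")
  out <- tibble(
    label = c(labels, sprintf(".pad%03d", seq_len(n_pad))),
    p = p_all, adjusted = adj,
    padded = c(rep(FALSE, n_real), rep(TRUE, n_pad))
  )
  attr(out, "m") <- m
  out
}

#' Holm step-down adjustment
#'
#' @inheritParams adjust_bh
#' @return A tibble (`label`, `p`, `adjusted`).
#' @examples
#' adjust_holm(c(0.002, 0.045, 0.2, 0.4, 0.9))$adjusted[1]  # 0.010
#' @export
adjust_holm <- function(p, labels = NULL) {
  assert_prob(p, "p")
  labels <- labels %||% as.character(seq_along(p))
  tibble(label = labels, p = p, adjusted = p.adjust(p, method = "holm"))
}

new_perm_result <- function(observed, null, framework, seed, n_perm,
                            smooth, extra = list()) {
  n_extreme <- vapply(names(observed), function(s)
    sum(null[[s]] >= observed[[s]]), numeric(1))
  p <- if (smooth) (n_extreme + 1) / (n_perm + 1) else n_extreme / n_perm
  structure(c(list(observed = observed, null = as_tibble(null),
                   p = as.list(p), n_perm = n_perm, framework = framework,
                   seed = seed, smooth = smooth), extra),
            class = "rg_perm")
}

#' @export
print.rg_perm <- function(x, ...) {
  cat(sprintf("<rg_perm:%s> N=%d%s\n", x$framework, x$n_perm,
              if (x$smooth) " (+1 smoothing)" else ""))
  for (s in names(x$observed)) {
    cat(sprintf("  %s: observed=%.4f p=%.4g\n", s, x$observed[[s]], x$p[[s]]))
  }
  invisible(x)
}

#' Patient-level permutation test for the mixed-model association
#'
#' Shuffles the mapping between patients' pathway scores and radiomic
#' features while preserving each patient's within-patient correlation
#' structure: a random patient permutation moves all of a patient's
#' pathway-score rows together, realigned to the receiving patient's
#' available subcompartments; rows without a counterpart subcompartment
#' are dropped for that permutation (permutations losing more than half
#' the rows are redrawn and counted). The features are fixed — the same
#' pre-selected set in every permutation. The full/null pair is refitted
#' for each permutation and the LRT chi-squared and marginal R2 recorded;
#' one-sided p-values are `n_extreme / N` by default (an observed
#' statistic exceeding every null value gives p = 0; `smooth = TRUE`
#' switches to `(n_extreme + 1) / (N + 1)`).
#'
#' @param data Analysis table from [build_analysis_table()].
#' @param features Radiomic feature columns (pre-selected, fixed).
#' @param covariates Covariates kept in both models.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed.
#' @param smooth Use add-one smoothing (default `FALSE`).
#' @return An `rg_perm` with statistics `chi2` and `r2m`.
#' @export
permute_lmm_patient <- function(data, features = attr(data, "features"),
                                covariates = character(0), n_perm = 1000,
                                seed = 42, smooth = FALSE) {
  obs_fit <- fit_lmm_pair(data, features = features,
                          covariates = covariates)
  patients <- levels(droplevels(data$patient_id))
  n_pat <- length(patients)
  score_rows <- data |>
    select("patient_id", "subcompartment", "z_pathway") |>
    mutate(patient_id = as.character(.data$patient_id))
  feat_rows <- data |>
    select(-"z_pathway") |>
    mutate(patient_id = as.character(.data$patient_id))
  redraws <- 0
  null_chi2 <- numeric(n_perm)
  null_r2m <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    attempt <- 0
    repeat {
      perm <- withr::with_seed(derive_seed(seed, "lmmperm", b, attempt),
                               sample(patients))
      names(perm) <- patients
      permuted <- feat_rows |>
        mutate(donor = unname(perm[.data$patient_id])) |>
        inner_join(score_rows,
                   by = c(donor = "patient_id", "subcompartment"))
      if (nrow(permuted) >= 0.5 * nrow(data)) break
      redraws <- redraws + 1
      attempt <- attempt + 1
    }
    permuted$patient_id <- factor(permuted$patient_id)
    fit <- fit_lmm_pair(permuted, features = features,
                        covariates = covariates)
    null_chi2[b] <- fit$chi2
    null_r2m[b] <- fit$r2m_full
  }
  new_perm_result(
    observed = list(chi2 = obs_fit$chi2, r2m = obs_fit$r2m_full),
    null = list(chi2 = null_chi2, r2m = null_r2m),
    framework = "patient_level_lmm", seed = seed, n_perm = n_perm,
    smooth = smooth, extra = list(redraws = redraws, fit = obs_fit))
}

#' Fully nested permutation test for the cross-validated elastic net
#'
#' Each permutation shuffles the pathway scores across patients and
#' re-executes the entire nested LOPO-CV pipeline, including the
#' univariate screen inside every fold, recording the permuted R2cv.
#' This accounts for the adaptive feature-selection process in the null
#' distribution. Intended for pathways with a positive observed R2cv
#' (set `force = TRUE` to run regardless).
#'
#' @param ptable Patient-level table.
#' @param set_name Gene set.
#' @param en_config,fdr_cut,cap As in [nested_lopo()].
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed.
#' @param smooth Add-one smoothing (default `FALSE`, the `n_extreme / N`
#'   convention).
#' @param force Run even when the observed R2cv <= 0.
#' @param observed Optional precomputed `rg_nestedcv` for the unpermuted
#'   data (avoids refitting).
#' @param permutations Optional explicit list of patient-index
#'   permutations (overrides `n_perm`; used for verification).
#' @return An `rg_perm` with statistic `r2_cv`.
#' @export
permute_nested_cv <- function(ptable, set_name,
                              en_config = elastic_net_config(),
                              fdr_cut = 0.10, cap = 5, n_perm = 1000,
                              seed = 42, smooth = FALSE, force = FALSE,
                              observed = NULL, permutations = NULL) {
  obs_cv <- observed %||% nested_lopo(ptable, set_name, en_config,
                                      fdr_cut = fdr_cut, cap = cap)
  if (obs_cv$r2_cv <= 0 && !force && is.null(permutations)) {
    abort("Observed R2cv <= 0; nested permutation skipped (use force = TRUE).")
  }
  n <- nrow(ptable)
  if (is.null(permutations)) {
    permutations <- lapply(seq_len(n_perm), function(b)
      withr::with_seed(derive_seed(seed, "nestperm", b), sample(n)))
  }
  n_perm <- length(permutations)
  # the permuted reruns use the same elastic-net seed as the observed run:
  # the inner-fold stratification already varies with the permuted response,
  # and the identity permutation must reproduce the observed statistic
  feats <- grep("^feat_", names(ptable), value = TRUE)
  X_all <- as.matrix(ptable[feats])
  rownames(X_all) <- NULL
  y_obs <- ptable[[set_name]]
  null_r2 <- vapply(seq_along(permutations), function(b) {
    lopo_r2(X_all, y_obs[permutations[[b]]], ptable$patient_id,
            en_config, fdr_cut, cap)
  }, numeric(1))
  new_perm_result(
    observed = list(r2_cv = obs_cv$r2_cv),
    null = list(r2_cv = null_r2),
    framework = "fully_nested_cv", seed = seed, n_perm = n_perm,
    smooth = smooth, extra = list(nestedcv = obs_cv))
}
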