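# Mixed-model association: standardization, variance components against a
# closed-form balanced-ANOVA oracle, R2 decomposition, ICC recovery,
# coefficient inference, campaign FDR padding, and the covariate ladder.

test_that("zscore matches hand values globally and within groups", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  z <- zscore(c(1, 3, 1, 3), group = c("a", "a", "b", "b"))
  expect_equal(z, rep(c(-1, 1) / sqrt(2), 2))
  expect_warning(zscore(c(2, 2, 2)), "Zero variance")
})

test_that("ML variance components match the closed-form balanced ANOVA", {
  # balanced one-way layout: a patients x m = 2 observations, intercept-only
  # mixed model. ML closed form: sigma_e^2 = SSW / (a (m-1)),
  # lambda = m * sum((ybar_i - ybar)^2) / a, sigma_b^2 = (lambda - s_e^2)/m.
  withr::with_seed(42, {
    a <- 40; m <- 2
    b <- rnorm(a, 0, 1.2)
    y <- rep(b, each = m) + rnorm(a * m, 0, 0.8)
  })
  d <- tibble::tibble(patient_id = factor(rep(seq_len(a), each = m)),
                      z_pathway = y)
  fit <- radpath:::fit_ml(z_pathway ~ 1 + (1 | patient_id), d)$fit
  vc <- lme4::VarCorr(fit)
  sigma_u2 <- as.numeric(vc$patient_id[1, 1])
  sigma_e2 <- stats::sigma(fit)^2

  ybar_i <- tapply(y, d$patient_id, mean)
  ssw <- sum((y - rep(ybar_i, each = m))^2)
  se2 <- ssw / (a * (m - 1))
  lambda <- m * sum((ybar_i - mean(y))^2) / a
  sb2 <- max(0, (lambda - se2) / m)
  expect_equal(sigma_e2, se2, tolerance = 1e-6)
  expect_equal(sigma_u2, sb2, tolerance = 1e-6)
})

test_that("ICC is recovered by construction", {
  # var(intercept) = var(residual) = 1 -> ICC ~ 0.5 at 200 patients
  d <- make_lmm_data(n_patients = 200, k = 1, beta = 0,
                     intercept_sd = 1, resid_sd = 1, seed = 77)
  fit <- fit_lmm_pair(d)
  expect_equal(fit$icc, 0.5, tolerance = 0.1)
  expect_gte(fit$icc, 0); expect_lte(fit$icc, 1)
})

test_that("a noiseless response drives R2m to 1 and the LRT p to 0", {
  d <- make_lmm_data(n_patients = 30, k = 1, beta = 0, seed = 5)
  d$z_pathway <- 2 * d$feat_0001
  fit <- fit_lmm_pair(d)
  expect_gt(fit$r2m_full, 0.99)
  expect_gt(fit$chi2, 50)
  expect_lt(fit$lrt_p, 1e-10)
})

test_that("R2 decomposition is invariant to response shifts and respects r2c >= r2m", {
  d <- make_lmm_data(n_patients = 25, k = 2, beta = c(0.5, 0), seed = 9)
  f1 <- fit_lmm_pair(d)
  d2 <- d; d2$z_pathway <- d2$z_pathway + 100
  f2 <- fit_lmm_pair(d2)
  expect_equal(f1$r2m_full, f2$r2m_full, tolerance = 1e-6)
  expect_equal(f1$r2c, f2$r2c, tolerance = 1e-6)
  expect_lte(f1$r2m_full, f1$r2c + 1e-9)
  expect_equal(f1$delta_r2m, f1$r2m_full - f1$r2m_null, tolerance = 1e-12)
  expect_gte(f1$chi2, 0)
})

test_that("coefficient table carries Wald inference and Holm correction", {
  d <- make_lmm_data(n_patients = 30, k = 3, beta = c(0.8, 0, 0), seed = 13)
  fit <- fit_lmm_pair(d)
  td <- tidy(fit)
  expect_equal(nrow(td), 3)
  expect_true(all(td$holm_p >= td$p_value))
  expect_equal(td$term[which.min(td$p_value)], "feat_0001")
  expect_true(all(td$conf_low < td$estimate & td$estimate < td$conf_high))
  g <- glance(fit)
  expect_equal(g$k, 3)
})

test_that("the campaign pads the FDR family and assigns p = 1 to empty pathways", {
  co <- small_cohort(seed = 19, couplings = list(
    coupling("SET_01", features = 35:37, signal_fraction = 0.6)))
  scores <- ssgsea_scores(co$expression, co$gene_sets,
                          samples = co$samples, kernel_transform = FALSE)
  obs <- aggregate_to_subcompartments(scores, zone_map())
  red <- co$radiomics |> near_zero_variance_filter() |> correlation_prune()
  camp <- run_lmm_campaign(obs, red, n_total = 24)
  res <- camp$results
  expect_equal(nrow(res), 4)
  empty <- res |> dplyr::filter(k == 0)
  expect_true(all(empty$lrt_p == 1))
  # padded BH: a single tested p of 0.001 against m = 24 would give 0.024;
  # check the arithmetic holds for the observed smallest p
  best <- res |> dplyr::slice_min(lrt_p, n = 1)
  if (best$k > 0 && best$lrt_p < min(res$lrt_p[res$k == 0])) {
    expect_equal(best$fdr, min(1, best$lrt_p * 24), tolerance = 1e-9)
  }
})

test_that("irrelevant covariates leave the radiomic LRT essentially unchanged", {
  d <- make_lmm_data(n_patients = 35, k = 2, beta = c(0.7, 0.3), seed = 21)
  withr::with_seed(22, {
    cov <- tibble::tibble(
      patient_id = levels(d$patient_id),
      age = rnorm(35, 58.5, 7.8),
      mgmt_methylated = rbinom(35, 1, 0.46),
      subtype = sample(c("Classical", "Mesenchymal", "Proneural"), 35,
                       replace = TRUE))
  })
  d2 <- dplyr::left_join(d, cov, by = "patient_id")
  attr(d2, "features") <- attr(d, "features")
  lad <- covariate_ladder(d2)
  expect_equal(lad$model, c("A", "B", "C", "D"))
  expect_true(all(lad$lrt_p < 0.05))
  # chi2 varies only within Monte-Carlo noise across the ladder
  expect_lt(diff(range(lad$chi2)) / lad$chi2[1], 0.5)
})

test_that("a planted subtype effect raises marginal R2 from model C to D", {
  d <- make_lmm_data(n_patients = 40, k = 1, beta = 0.4, seed = 31)
  withr::with_seed(32, {
    cov <- tibble::tibble(
      patient_id = levels(d$patient_id),
      age = rnorm(40, 58.5, 7.8),
      mgmt_methylated = rbinom(40, 1, 0.46),
      subtype = sample(c("Classical", "Mesenchymal", "Proneural"), 40,
                       replace = TRUE))
  })
  shift <- c(Classical = -1, Mesenchymal = 0, Proneural = 1)
  d2 <- dplyr::left_join(d, cov, by = "patient_id")
  d2$z_pathway <- d2$z_pathway + shift[d2$subtype]
  attr(d2, "features") <- attr(d, "features")
  lad <- covariate_ladder(d2)
  expect_gt(lad$r2m_full[lad$model == "D"], lad$r2m_full[lad$model == "C"])
})

test_that("missing covariates are an error and diagnostics are reported", {
  d <- make_lmm_data(n_patients = 20, k = 1, beta = 0.5, seed = 41)
  expect_error(covariate_ladder(d), "missing")
  fit <- fit_lmm_pair(d)
  diag <- lmm_diagnostics(fit, d)
  expect_true(is.numeric(diag$shapiro_p))
  expect_equal(nrow(diag$influence), nrow(d))
  expect_true(all(is.finite(diag$influence$max_std_change)))
})
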