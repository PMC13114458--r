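# Feature reduction: near-zero-variance rule, deterministic correlation
# pruning, the supervised screen, and its leakage guarantees.

rad_table <- function(X, patients = NULL) {
  n <- nrow(X)
  dplyr::bind_cols(
    tibble::tibble(patient_id = patients %||% sprintf("P%03d", seq_len(n)),
                   subcompartment = "ET"),
    tibble::as_tibble(as.data.frame(X)))
}

test_that("near-zero-variance rule drops constant and lopsided columns", {
  withr::with_seed(1, {
    X <- data.frame(
      constant = rep(7, 50),
      lopsided = c(rep(0, 48), 1, 1),     # ratio 24 > 19, 4% unique < 10
      healthy = seq_len(50),
      noisy = rnorm(50))
  })
  out <- near_zero_variance_filter(rad_table(X))
  kept <- setdiff(names(out), c("patient_id", "subcompartment"))
  expect_setequal(kept, c("healthy", "noisy"))
  st <- reduction_stages(out)
  expect_equal(st$n_dropped, 2L)
})

test_that("correlation pruning keeps one of each duplicated/collinear group", {
  withr::with_seed(2, {
    base <- rnorm(30)
    X <- data.frame(a = base, b = base, c = -base,
                    d = rnorm(30), e = rnorm(30))
  })
  out <- correlation_prune(rad_table(X), rho_cut = 0.9)
  kept <- setdiff(names(out), c("patient_id", "subcompartment"))
  # exactly one of the three mutually |rho| = 1 columns survives
  expect_length(intersect(kept, c("a", "b", "c")), 1)
  expect_true(all(c("d", "e") %in% kept))
  # brute force: whatever removal order is used on a mutually |rho|=1
  # trio, exactly one member can survive with all pairwise |rho| <= cut
  for (drop2 in utils::combn(c("a", "b", "c"), 2, simplify = FALSE)) {
    surv <- setdiff(c("a", "b", "c"), drop2)
    C <- abs(cor(X[c(surv, "d", "e")], method = "spearman"))
    diag(C) <- 0
    expect_lte(max(C), 0.9)
  }
})

test_that("weakly correlated tables pass through unchanged", {
  withr::with_seed(3, X <- matrix(rnorm(40 * 6), 40))
  colnames(X) <- letters[1:6]
  tab <- rad_table(X)
  out <- correlation_prune(tab, rho_cut = 0.95)
  expect_setequal(setdiff(names(out), c("patient_id", "subcompartment")),
                  letters[1:6])
})

test_that("pruning is invariant to column order", {
  withr::with_seed(4, {
    z <- rnorm(25)
    X <- data.frame(f1 = z + 0.1 * rnorm(25), f2 = z + 0.1 * rnorm(25),
                    f3 = z + 0.1 * rnorm(25), f4 = rnorm(25))
  })
  k1 <- correlation_prune(rad_table(X), 0.8)
  k2 <- correlation_prune(rad_table(X[, c(3, 1, 4, 2)]), 0.8)
  expect_setequal(
    setdiff(names(k1), c("patient_id", "subcompartment")),
    setdiff(names(k2), c("patient_id", "subcompartment")))
})

test_that("stage survivor counts are monotonically nonincreasing", {
  co <- small_cohort(seed = 6)
  red <- co$radiomics |>
    near_zero_variance_filter() |>
    correlation_prune()
  st <- reduction_stages(red)
  expect_equal(st$stage, c("near_zero_variance", "correlation_prune"))
  expect_true(all(st$n_after <= st$n_before))
  expect_equal(st$n_before[2], st$n_after[1])
})

test_that("unsupervised stages never look at outcomes", {
  co <- small_cohort(seed = 7)
  r1 <- co$radiomics |> near_zero_variance_filter() |> correlation_prune()
  # permuting any pathway-score table cannot change stages 1-2: they take
  # no outcome argument; assert output is a pure function of the features
  r2 <- co$radiomics |> near_zero_variance_filter() |> correlation_prune()
  expect_identical(names(r1), names(r2))
})

test_that("screen ranks by raw p under the FDR gate, capped at five", {
  withr::with_seed(11, {
    n <- 40
    y <- rnorm(n)
    X <- matrix(rnorm(n * 20), n)
    colnames(X) <- sprintf("feat_%04d", 1:20)
    X[, 1] <- y + 0.2 * rnorm(n)   # strongest
    X[, 2] <- y + 0.5 * rnorm(n)
    X[, 3] <- y + 0.8 * rnorm(n)
  })
  tab <- rad_table(X)
  scr <- univariate_screen(tab[-2],
                           tibble::tibble(patient_id = tab$patient_id,
                                          score = y),
                           mode = "patient_level")
  expect_lte(length(scr$selected), 5)
  expect_equal(scr$selected[1], "feat_0001")
  expect_true(all(c("feat_0002", "feat_0003") %in% scr$selected))
  expect_true(all(tidy(scr)$min_fdr[tidy(scr)$selected] < 0.10))
})

test_that("null screens come back empty most of the time", {
  sizes <- purrr::map_int(1:10, function(s) {
    withr::with_seed(600 + s, {
      X <- matrix(rnorm(30 * 50), 30)
      colnames(X) <- sprintf("feat_%04d", 1:50)
      y <- rnorm(30)
    })
    tab <- rad_table(X)
    length(univariate_screen(tab[-2],
                             tibble::tibble(patient_id = tab$patient_id,
                                            score = y),
                             mode = "patient_level")$selected)
  })
  expect_gte(mean(sizes == 0), 0.7)
})

test_that("a strongly coupled feature is selected first at cohort scale", {
  hits <- purrr::map_lgl(1:20, function(s) {
    withr::with_seed(700 + s, {
      n <- 28
      a <- rnorm(n)
      X <- matrix(rnorm(n * 30), n)
      colnames(X) <- sprintf("feat_%04d", 1:30)
      X[, 7] <- a + rnorm(n, 0, sqrt(1 / 0.81 - 1))  # population rho ~ 0.9
    })
    tab <- rad_table(X)
    scr <- univariate_screen(tab[-2],
                             tibble::tibble(patient_id = tab$patient_id,
                                            score = a),
                             mode = "patient_level")
    length(scr$selected) > 0 && scr$selected[1] == "feat_0007"
  })
  expect_gte(mean(hits), 0.95)
})

test_that("per-subcompartment mode computes FDR within each subcompartment", {
  co <- small_cohort(seed = 8, couplings = list(
    coupling("SET_01", features = 30, signal_fraction = 0.8)))
  scores <- ssgsea_scores(co$expression, co$gene_sets, samples = co$samples,
                          kernel_transform = FALSE)
  obs <- aggregate_to_subcompartments(scores, zone_map())
  scr <- univariate_screen(co$radiomics, obs, set_name = "SET_01",
                           mode = "per_subcompartment")
  expect_true(all(scr$table$group %in% c("ET", "NET", "ED")))
  expect_true("feat_0030" %in% scr$selected)
  # small subcompartments are screened with the exact/approximate split
  expect_true(all(is.finite(scr$table$p)
                  | is.na(scr$table$p)))
})

test_that("in-fold screening never sees the held-out patient (leakage canary)", {
  pt <- make_ptable(n_patients = 16, n_features = 25, seed = 9,
                    signal = 1.2, n_signal = 3)
  held <- pt$patient_id[1]
  train <- pt |> dplyr::filter(patient_id != held)
  feats <- grep("^feat_", names(pt), value = TRUE)
  sel1 <- univariate_screen(train[c("patient_id", feats)],
                            train[c("patient_id", "score")],
                            mode = "patient_level")$selected
  # flip the held-out patient's score wildly; the fold selection must not move
  pt2 <- pt
  pt2$score[pt2$patient_id == held] <- 1e3
  train2 <- pt2 |> dplyr::filter(patient_id != held)
  sel2 <- univariate_screen(train2[c("patient_id", feats)],
                            train2[c("patient_id", "score")],
                            mode = "patient_level")$selected
  expect_identical(sel1, sel2)
})
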