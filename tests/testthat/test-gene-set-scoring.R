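# Scoring: log transform, the running-sum enrichment score and its rank
# invariances, zone-module derivation, and Jaccard overlap.

toy_expr <- function(values, genes = sprintf("g%d", seq_along(values))) {
  tibble::tibble(gene_id = genes, s1 = values)
}

test_that("log2(FPKM + 1) transform matches hand values and rejects negatives", {
  expr <- toy_expr(c(0, 1, 7))
  out <- log2_fpkm(expr)
  expect_equal(out$s1, c(0, 1, 3))
  expect_error(log2_fpkm(toy_expr(c(-1, 2, 3))), ">= 0")
})

test_that("unweighted running sum reproduces the hand-computed score", {
  expr <- toy_expr(c(8, 4, 2))
  sets <- tibble::tibble(set_name = "up", category = "custom",
                         genes = list("g1"))
  sc <- ssgsea_scores(expr, sets, weight_exponent = 0,
                      kernel_transform = FALSE, normalize = FALSE)
  expect_equal(sc$score, 1.5)  # (1-0) + (1-1/2) + (1-1)
})

test_that("a set containing all genes has zero out-of-set mass and positive score", {
  expr <- toy_expr(c(8, 4, 2))
  sets <- tibble::tibble(set_name = "all", category = "custom",
                         genes = list(c("g1", "g2", "g3")))
  sc <- ssgsea_scores(expr, sets, weight_exponent = 0.25,
                      kernel_transform = FALSE, normalize = FALSE)
  expect_gt(sc$score, 0)
})

test_that("scores are invariant to strictly monotone transforms when kernel is off", {
  withr::with_seed(8, {
    expr <- tibble::tibble(gene_id = sprintf("g%02d", 1:30),
                           s1 = runif(30, 0, 50), s2 = runif(30, 0, 50))
  })
  sets <- tibble::tibble(set_name = c("a", "b"), category = "custom",
                         genes = list(sprintf("g%02d", 1:6),
                                      sprintf("g%02d", 11:18)))
  base <- ssgsea_scores(expr, sets, kernel_transform = FALSE,
                        normalize = FALSE)
  trans <- expr
  trans[c("s1", "s2")] <- lapply(trans[c("s1", "s2")],
                                 function(x) exp(x / 10) - 1)
  again <- ssgsea_scores(trans, sets, kernel_transform = FALSE,
                         normalize = FALSE)
  expect_equal(again$score, base$score, tolerance = 1e-12)
})

test_that("exponent-0 cumulative fractions both reach 1 at the final rank", {
  # equivalent assertion: for the degenerate one-gene universe split, the
  # final running difference is 0, i.e. score of set A + score of its
  # complement's out-of-set contribution cancel at the last position.
  withr::with_seed(4, {
    expr <- tibble::tibble(gene_id = sprintf("g%02d", 1:12),
                           s1 = runif(12, 0, 20))
  })
  in_set <- sprintf("g%02d", c(2, 5, 9))
  sets <- tibble::tibble(set_name = c("A", "comp"), category = "custom",
                         genes = list(in_set,
                                      setdiff(expr$gene_id, in_set)))
  sc <- ssgsea_scores(expr, sets, weight_exponent = 0,
                      kernel_transform = FALSE, normalize = FALSE)
  # P_in(final) = P_out(final) = 1 for both sets => running sums are
  # exact mirror images: ES(A) = -ES(complement)
  expect_equal(sc$score[sc$set_name == "A"],
               -sc$score[sc$set_name == "comp"], tolerance = 1e-12)
})

test_that("absent genes are dropped with a warning; fully absent sets are skipped", {
  expr <- toy_expr(c(5, 3, 1))
  sets <- tibble::tibble(
    set_name = c("partial", "gone"), category = "custom",
    genes = list(c("g1", "nope"), c("missing1", "missing2")))
  expect_warning(expect_warning(
    sc <- ssgsea_scores(expr, sets, kernel_transform = FALSE),
    "absent"), "Skipping")
  expect_setequal(unique(sc$set_name), "partial")
})

test_that("kernel transform changes cross-gene ordering but keeps determinism", {
  withr::with_seed(2, {
    expr <- tibble::tibble(gene_id = sprintf("g%02d", 1:20),
                           s1 = runif(20, 0, 9), s2 = runif(20, 0, 9),
                           s3 = runif(20, 0, 9))
  })
  sets <- tibble::tibble(set_name = "a", category = "custom",
                         genes = list(sprintf("g%02d", 1:5)))
  k1 <- ssgsea_scores(expr, sets, kernel_transform = TRUE)
  k2 <- ssgsea_scores(expr, sets, kernel_transform = TRUE)
  expect_identical(k1, k2)
})

test_that("zone modules recover planted zone-shifted genes and stay within top_k", {
  # 2 zones x 20 samples; genes 1-10 shifted +2 log2 units in zone CT.
  # Recovery is exact in the vast majority of seeds (a gene whose realized
  # shift lands at the |delta| > 1 / FDR < 0.05 boundary can drop out), and
  # the module never contains an unshifted gene.
  planted <- sprintf("g%02d", 1:10)
  run_one <- function(seed, top_k = 200) {
    n_per <- 20
    withr::with_seed(seed, {
      lg <- matrix(rnorm(80 * 2 * n_per, 4, 1), nrow = 80)
      lg[1:10, 1:n_per] <- lg[1:10, 1:n_per] + 2
    })
    samples <- tibble::tibble(
      sample_id = sprintf("s%02d", 1:(2 * n_per)),
      patient_id = sprintf("P%02d", 1:(2 * n_per)),
      zone = rep(c("CT", "IT"), each = n_per))
    expr <- dplyr::bind_cols(
      tibble::tibble(gene_id = sprintf("g%02d", 1:80)),
      tibble::as_tibble(matrix(pmax(2^lg - 1, 0), nrow = 80,
                               dimnames = list(NULL, samples$sample_id)),
                        .name_repair = "minimal"))
    derive_zone_modules(expr, samples, top_k = top_k)
  }
  mods_list <- purrr::map(31:50, run_one)
  ct_sets <- purrr::map(mods_list, function(m)
    m$genes[[which(m$set_name == "module_CT")]])
  expect_gte(sum(purrr::map_lgl(ct_sets, setequal, planted)), 16)
  # precision stays essentially perfect (BH admits rare false discoveries)
  precision <- purrr::map_dbl(ct_sets, function(g) mean(g %in% planted))
  expect_gte(mean(precision), 0.95)
  expect_true(all(purrr::map_lgl(mods_list, function(m)
    all(lengths(m$genes) <= 200 & m$category == "ivygap_module"))))
  # truncation at top_k
  mods3 <- run_one(31, top_k = 3)
  expect_true(all(lengths(mods3$genes) <= 3))
})

test_that("exchangeable zones yield empty modules", {
  withr::with_seed(17, {
    lg <- matrix(rnorm(60 * 30, 4, 1), nrow = 60)
  })
  samples <- tibble::tibble(sample_id = sprintf("s%02d", 1:30),
                            patient_id = sprintf("P%02d", 1:30),
                            zone = rep(c("CT", "LE"), each = 15))
  expr <- dplyr::bind_cols(
    tibble::tibble(gene_id = sprintf("g%02d", 1:60)),
    tibble::as_tibble(matrix(pmax(2^lg - 1, 0), nrow = 60,
                             dimnames = list(NULL, samples$sample_id)),
                      .name_repair = "minimal"))
  mods <- derive_zone_modules(expr, samples)
  expect_equal(nrow(mods), 0L)
})

test_that("the vectorised Wilcoxon matches stats::wilcox.test", {
  withr::with_seed(5, {
    mat <- matrix(c(rnorm(40), sample(1:4, 40, TRUE)), nrow = 2,
                  byrow = TRUE)  # second row has heavy ties
    grp <- rep(c(TRUE, FALSE), each = 20)
  })
  ours <- radpath:::wilcoxon_rows(mat, grp)
  ref <- apply(mat, 1, function(x)
    suppressWarnings(stats::wilcox.test(x[grp], x[!grp], exact = FALSE,
                                        correct = TRUE)$p.value))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("Jaccard matrix matches direct counts and is symmetric with unit diagonal", {
  sets <- tibble::tibble(
    set_name = c("A", "B", "C", "D"), category = "custom",
    genes = list(c("a", "b", "c"), c("b", "c", "d"), c("x", "y"),
                 c("a", "b", "c")))
  J <- jaccard_matrix(sets)
  expect_equal(J["A", "B"], 0.5)   # 2 / 4
  expect_equal(J["A", "C"], 0)     # disjoint
  expect_equal(J["A", "D"], 1)     # identical
  expect_equal(J, t(J))
  expect_equal(unname(diag(J)), rep(1, 4))
  # growing the intersection (superset of B's overlap with A) cannot
  # decrease J when the union stays fixed
  sets2 <- sets
  sets2$genes[[2]] <- c("a", "b", "c", "d")
  expect_gte(jaccard_matrix(sets2)["A", "B"], J["A", "B"])
})
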