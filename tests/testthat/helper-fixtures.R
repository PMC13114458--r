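# Fixtures built in code: small cohorts, direct analysis tables, and a
# lightweight elastic-net configuration for fast cross-validation tests.

fast_en <- function(seed = 42) {
  elastic_net_config(alpha_grid = c(0.2, 0.5, 1), n_lambda = 40,
                     seed = seed)
}

small_cohort <- function(seed = 1, couplings = list(), ...) {
  generate_cohort(cohort_config(
    n_genes = 120, n_gene_sets = 4, genes_per_set = 12,
    n_features = 40, n_nzv_features = 3, n_corr_blocks = 2, block_size = 3,
    couplings = couplings, seed = seed, ...))
}

# Patient-level table with iid-normal candidate features and a response;
# `signal` couples the first `n_signal` features linearly to the response.
make_ptable <- function(n_patients = 20, n_features = 30, seed = 1,
                        signal = 0, n_signal = 2, noise = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n_patients * n_features), n_patients)
    colnames(X) <- sprintf("feat_%04d", seq_len(n_features))
    a <- rnorm(n_patients)
    y <- a + rnorm(n_patients, 0, noise)
    if (signal != 0 && n_signal > 0) {
      for (j in seq_len(n_signal)) X[, j] <- signal * a + rnorm(n_patients)
    }
    dplyr::bind_cols(
      tibble::tibble(patient_id = sprintf("P%03d", seq_len(n_patients)),
                     score = as.numeric(scale(y))),
      tibble::as_tibble(X, .name_repair = "minimal"))
  })
}

# Observation-level analysis table generated directly from the mixed-model
# data-generating process: z_pathway = X beta + patient intercept + noise.
make_lmm_data <- function(n_patients = 25, k = 2, beta = rep(0, k),
                          intercept_sd = 0.7, resid_sd = 1, seed = 1,
                          subcompartments = c("ET", "NET", "ED")) {
  withr::with_seed(seed, {
    rows <- purrr::map_dfr(seq_len(n_patients), function(i) {
      subs <- subcompartments[seq_len(sample(2:3, 1))]
      tibble::tibble(patient_id = sprintf("P%03d", i),
                     subcompartment = subs)
    })
    n <- nrow(rows)
    X <- matrix(rnorm(n * k), n)
    colnames(X) <- sprintf("feat_%04d", seq_len(k))
    u <- stats::setNames(rnorm(n_patients, 0, intercept_sd),
                         sprintf("P%03d", seq_len(n_patients)))
    y <- as.numeric(X %*% beta) + u[rows$patient_id] + rnorm(n, 0, resid_sd)
    d <- dplyr::bind_cols(rows, tibble::as_tibble(X, .name_repair = "minimal"))
    d$z_pathway <- y
    d$subcompartment <- factor(d$subcompartment,
                               levels = c("ET", "NET", "ED"))
    d$patient_id <- factor(d$patient_id)
    attr(d, "features") <- colnames(X)
    d
  })
}

# Long score table (one set) built directly, bypassing expression scoring.
make_scores <- function(samples, values, set_name = "SET_01") {
  tibble::tibble(sample_id = samples$sample_id,
                 patient_id = samples$patient_id,
                 zone = samples$zone,
                 set_name = set_name,
                 score = values)
}
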