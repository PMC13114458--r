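# End-to-end orchestration: scoring -> mapping -> reduction -> mixed-model
# campaign -> nested CV for every gene set -> permutations -> corrections,
# with deterministic seeding, a config hash, and CSV/JSON reporting.

#' Study configuration
#'
#' @param map Zone map (default the primary CT/CTmvp->ET, CTpan->NET,
#'   IT/LE->ED map with mean aggregation).
#' @param weight_exponent,kernel_transform,normalize Scoring settings
#'   passed to [ssgsea_scores()].
#' @param nzv_freq_ratio,nzv_unique_pct,rho_cut Unsupervised reduction
#'   thresholds.
#' @param screen_fdr,screen_cap Supervised screening thresholds (0.10, 5).
#' @param en Elastic net configuration.
#' @param n_perm_lmm,n_perm_nested Permutation sizes (defaults 1000; use
#'   the 99/199 desk presets for quick runs). Must be >= 19.
#' @param lmm_fdr_threshold,nested_fdr_threshold Interpretive FDR
#'   thresholds for the two frameworks (0.05 and 0.10).
#' @param n_total_pathways FDR family size for the padded corrections
#'   (default: the number of scored sets).
#' @param run_permutations Run the permutation stages (default `TRUE`;
#'   nested permutations run only for sets with positive R2cv).
#' @param seed Run seed; every stochastic step derives its seed from it.
#' @return A `study_config` list.
#' @export
study_config <- function(map = zone_map(),
                         weight_exponent = 0.25, kernel_transform = TRUE,
                         normalize = TRUE,
                         nzv_freq_ratio = 95 / 5, nzv_unique_pct = 10,
                         rho_cut = 0.90,
                         screen_fdr = 0.10, screen_cap = 5,
                         en = elastic_net_config(),
                         n_perm_lmm = 1000, n_perm_nested = 1000,
                         lmm_fdr_threshold = 0.05,
                         nested_fdr_threshold = 0.10,
                         n_total_pathways = NULL,
                         run_permutations = TRUE,
                         seed = 42) {
  stopifnot(screen_fdr > 0, screen_fdr < 1, n_perm_lmm >= 19,
            n_perm_nested >= 19)
  structure(list(
    map = map, weight_exponent = weight_exponent,
    kernel_transform = kernel_transform, normalize = normalize,
    nzv_freq_ratio = nzv_freq_ratio, nzv_unique_pct = nzv_unique_pct,
    rho_cut = rho_cut, screen_fdr = screen_fdr, screen_cap = screen_cap,
    en = en, n_perm_lmm = n_perm_lmm, n_perm_nested = n_perm_nested,
    lmm_fdr_threshold = lmm_fdr_threshold,
    nested_fdr_threshold = nested_fdr_threshold,
    n_total_pathways = n_total_pathways,
    run_permutations = run_permutations, seed = as.integer(seed)
  ), class = "study_config")
}

#' Run the full radiogenomic association study
#'
#' Executes, in order: gene-set scoring of the expression data, zone to
#' subcompartment aggregation, unsupervised radiomic feature reduction
#' (near-zero variance, correlation pruning), the mixed-model campaign
#' with full-data screening and padded FDR, the nested LOPO-CV elastic
#' net for every gene set (in-fold screening), nested permutation tests
#' for sets with positive R2cv plus the patient-level permutation for the
#' top mixed-model set, and both FDR reports (padded family and
#' restricted to the tested sets). Patient identifiers are intersected
#' across tables and the matched count reported; an empty intersection is
#' fatal.
#'
#' @param cohort An `rg_cohort`, or a list with `expression`, `samples`,
#'   `gene_sets`, `radiomics` (and optionally `covariates`), e.g. from
#'   [read_cohort()].
#' @param config A [study_config()].
#' @param output_dir Optional directory: writes `cv_results.csv`
#'   (nested-CV table), `lmm_results.csv` (association table),
#'   `reduction_stages.csv` and `manifest.json` (config hash, seed,
#'   matched patients).
#' @return An `rg_study` list: `scores`, `obs`, `radiomics_reduced`,
#'   `lmm` (campaign), `cv` (per-set `rg_nestedcv`), `cv_table`,
#'   `permutations`, `matched_patients`, `config`, `config_hash`.
#' @export
run_radiogenomic_study <- function(cohort, config = study_config(),
                                   output_dir = NULL) {
  hash <- config_hash(unclass(config))
  expr_pat <- unique(cohort$samples$patient_id)
  rad_pat <- unique(cohort$radiomics$patient_id)
  matched <- intersect(expr_pat, rad_pat)
  if (!length(matched)) abort("No patient ids shared between tables.")
  if (length(matched) < length(expr_pat) || length(matched) < length(rad_pat)) {
    inform(sprintf("Patient matching: %d expression x %d radiomics -> %d matched.",
                   length(expr_pat), length(rad_pat), length(matched)))
  }
  samples <- cohort$samples |> filter(.data$patient_id %in% matched)
  expression <- cohort$expression[c("gene_id", samples$sample_id)]
  radiomics <- cohort$radiomics |> filter(.data$patient_id %in% matched)

  scores <- ssgsea_scores(expression, cohort$gene_sets, samples = samples,
                          weight_exponent = config$weight_exponent,
                          kernel_transform = config$kernel_transform,
                          normalize = config$normalize)
  obs <- aggregate_to_subcompartments(scores, config$map)

  red <- radiomics |>
    near_zero_variance_filter(config$nzv_freq_ratio,
                              config$nzv_unique_pct) |>
    correlation_prune(config$rho_cut)

  sets <- unique(obs$set_name)
  n_total <- config$n_total_pathways %||% length(sets)
  categories <- setNames(cohort$gene_sets$category,
                         cohort$gene_sets$set_name)

  lmm <- run_lmm_campaign(obs, red, sets = sets, n_total = n_total,
                          fdr_cut = config$screen_fdr,
                          cap = config$screen_cap,
                          categories = categories)

  ptable <- patient_level_table(obs, red,
                                aggregate = config$map$aggregation)
  feats <- feature_columns(red)
  en <- config$en
  cv <- purrr::map(sets, function(s) {
    cfg <- en
    cfg$seed <- derive_seed(config$seed, "nested", s)
    nested_lopo(ptable, s, cfg, fdr_cut = config$screen_fdr,
                cap = config$screen_cap, feature_cols = feats)
  })
  names(cv) <- sets
  cv <- purrr::imap(cv, function(x, s) {
    x$boot_ci <- bootstrap_ci(x, B = 1000,
                              seed = derive_seed(config$seed, "boot", s))
    x
  })

  perms <- list()
  cv_p <- setNames(rep(1.0, length(sets)), sets)
  if (config$run_permutations) {
    for (s in sets) {
      if (cv[[s]]$r2_cv > 0) {
        pr <- permute_nested_cv(ptable, s, en_config = en,
                                fdr_cut = config$screen_fdr,
                                cap = config$screen_cap,
                                n_perm = config$n_perm_nested,
                                seed = derive_seed(config$seed, "nperm", s),
                                observed = cv[[s]])
        perms[[paste0("nested_", s)]] <- pr
        cv_p[s] <- pr$p$r2_cv
      }
    }
    top <- lmm$results |> filter(.data$k > 0) |> slice_min(.data$lrt_p, n = 1)
    if (nrow(top) == 1) {
      s <- top$set_name
      d <- build_analysis_table(obs, red, lmm$screens[[s]]$selected, s)
      perms[[paste0("lmm_", s)]] <-
        permute_lmm_patient(d, n_perm = config$n_perm_lmm,
                            seed = derive_seed(config$seed, "lperm", s))
    }
  }

  tested <- names(cv_p)[vapply(cv, function(x) x$r2_cv > 0, logical(1))]
  fdr_padded <- adjust_bh(unname(cv_p[tested]), labels = tested,
                          m = max(n_total, length(tested)))
  fdr_restricted <- if (length(tested))
    adjust_bh(unname(cv_p[tested]), labels = tested) else tibble()

  cv_table <- purrr::map_dfr(sets, function(s) {
    x <- cv[[s]]
    tibble(set_name = s,
           category = unname(categories[s]),
           r2_cv = x$r2_cv, ci_low = x$boot_ci$lower,
           ci_high = x$boot_ci$upper, mae = x$mae,
           spearman_rho = x$spearman_rho,
           n_stable = length(x$stable_set),
           perm_p = if (s %in% tested) cv_p[[s]] else NA_real_,
           fdr = if (s %in% tested)
             fdr_padded$adjusted[match(s, fdr_padded$label)] else NA_real_,
           status = x$status)
  }) |> arrange(desc(.data$r2_cv))

  study <- structure(list(
    scores = scores, obs = obs, radiomics_reduced = red,
    reduction = reduction_stages(red), lmm = lmm, cv = cv,
    cv_table = cv_table, fdr_restricted = fdr_restricted,
    permutations = perms, ptable = ptable,
    matched_patients = matched, config = config, config_hash = hash
  ), class = "rg_study")

  if (!is.null(output_dir)) write_study(study, output_dir)
  study
}

#' @export
print.rg_study <- function(x, ...) {
  cat(sprintf("<rg_study> %d patients, %d gene sets, config %s\n",
              length(x$matched_patients), nrow(x$cv_table),
              substr(x$config_hash, 1, 8)))
  cat("Nested CV (top rows):\n")
  print(head(x$cv_table, 5))
  invisible(x)
}

write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(study$cv_table, file.path(dir, "cv_results.csv"))
  readr::write_csv(study$lmm$results, file.path(dir, "lmm_results.csv"))
  readr::write_csv(study$reduction, file.path(dir, "reduction_stages.csv"))
  jsonlite::write_json(
    list(config_hash = study$config_hash, seed = study$config$seed,
         matched_patients = length(study$matched_patients),
         n_sets = nrow(study$cv_table),
         timestamp = NULL),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
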