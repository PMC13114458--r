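# Synthetic cohorts with the statistical structure of the zone-resolved
# radiogenomic design: unbalanced zone availability, FPKM expression with
# set-coherent zone shifts and per-patient pathway activity, radiomic tables
# with near-zero-variance and correlated feature blocks, and linear
# pathway-feature couplings with configurable effect size.

#' Configuration for a synthetic radiogenomic cohort
#'
#' Defaults reproduce the observation design of the motivating cohort:
#' 28 patients, cellular tumor (CT) sampled in all of them, microvascular
#' proliferation (CTmvp) in 9, pseudopalisading necrosis (CTpan) in 15,
#' and 7 patients with an infiltrating-tumor/leading-edge (IT/LE) sample,
#' 6 of whom also carry CTpan — which yields, after the primary
#' zone-to-subcompartment mapping, 50 patient-by-subcompartment observations
#' (ET n = 28, NET n = 15, ED n = 7) with 6 of 28 patients covering all
#' three subcompartments.
#'
#' @param n_patients Number of patients.
#' @param n_ctmvp,n_net,n_ed Number of patients with a CTmvp sample, a CTpan
#'   sample, and at least one IT/LE sample. For `n_patients` different from
#'   28 the defaults scale proportionally.
#' @param n_all_three Number of ED patients that also carry CTpan (drives
#'   the count of patients with all three subcompartments).
#' @param n_genes Number of genes.
#' @param n_gene_sets,genes_per_set Gene-set collection layout; sets are
#'   disjoint gene blocks. With the default 24 sets, the first 15 are
#'   labelled `hallmark`, the next 4 `neftel`, the last 5 `ivygap_module`.
#' @param zone_profile_sd SD of the per-set, per-zone mean shift (log2
#'   units); creates the zone-differential structure the zone modules and
#'   subcompartment fixed effect rely on.
#' @param activity_sd SD of the per-patient latent pathway activity; the
#'   activity shifts all genes of the set in all of the patient's samples
#'   and is the "true pathway signal" that planted couplings transmit.
#' @param expression_noise_sd Per-gene, per-sample residual SD (log2 units).
#' @param gene_base_mean,gene_base_sd Distribution of per-gene baseline
#'   log2 expression.
#' @param n_features Number of radiomic features (`feat_0001`, ...).
#' @param n_nzv_features Number of near-zero-variance features (a single
#'   repeated value in at least `nzv_fraction` of rows).
#' @param nzv_fraction Fraction of rows carrying the repeated value.
#' @param n_corr_blocks,block_size,within_block_rho Highly correlated
#'   feature blocks: each block shares a latent row value so that pairwise
#'   correlations are approximately `within_block_rho`.
#' @param patient_sd SD of the per-patient random intercept added to every
#'   radiomic feature (induces within-patient correlation, hence a nonzero
#'   ICC downstream).
#' @param couplings List of couplings created with [coupling()].
#' @param age_mean,age_sd,mgmt_prob Covariate moments (age truncated to
#'   \[30, 85\]; MGMT methylation probability 13/28 by default).
#' @param seed Integer run seed; all randomness derives from it.
#' @return A `cohort_config` list, validated.
#' @seealso [generate_cohort()], [coupling()]
#' @export
cohort_config <- function(n_patients = 28,
                          n_ctmvp = NULL, n_net = NULL, n_ed = NULL,
                          n_all_three = NULL,
                          n_genes = 600,
                          n_gene_sets = 24,
                          genes_per_set = 20,
                          zone_profile_sd = 1,
                          activity_sd = 1,
                          expression_noise_sd = 1,
                          gene_base_mean = 4,
                          gene_base_sd = 1.5,
                          n_features = 120,
                          n_nzv_features = 5,
                          nzv_fraction = 0.96,
                          n_corr_blocks = 3,
                          block_size = 4,
                          within_block_rho = 0.95,
                          patient_sd = 0.5,
                          couplings = list(),
                          age_mean = 58.5, age_sd = 7.8,
                          mgmt_prob = 13 / 28,
                          seed = 42) {
  scale_count <- function(k28) max(1L, round(n_patients * k28 / 28))
  n_ctmvp <- n_ctmvp %||% scale_count(9)
  n_net <- n_net %||% scale_count(15)
  n_ed <- n_ed %||% scale_count(7)
  n_all_three <- n_all_three %||% min(n_ed - 1L, n_net, scale_count(6))

  cfg <- list(
    n_patients = as.integer(n_patients), n_ctmvp = as.integer(n_ctmvp),
    n_net = as.integer(n_net), n_ed = as.integer(n_ed),
    n_all_three = as.integer(n_all_three),
    n_genes = as.integer(n_genes), n_gene_sets = as.integer(n_gene_sets),
    genes_per_set = as.integer(genes_per_set),
    zone_profile_sd = zone_profile_sd, activity_sd = activity_sd,
    expression_noise_sd = expression_noise_sd,
    gene_base_mean = gene_base_mean, gene_base_sd = gene_base_sd,
    n_features = as.integer(n_features),
    n_nzv_features = as.integer(n_nzv_features),
    nzv_fraction = nzv_fraction,
    n_corr_blocks = as.integer(n_corr_blocks),
    block_size = as.integer(block_size),
    within_block_rho = within_block_rho,
    patient_sd = patient_sd, couplings = couplings,
    age_mean = age_mean, age_sd = age_sd, mgmt_prob = mgmt_prob,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

#' Declare a planted pathway-feature coupling
#'
#' A coupled feature is generated as
#' `beta * activity + patient_intercept + N(0, sigma)`, where `activity` is
#' the patient's latent pathway activity for `set` (SD `activity_sd`, 1 by
#' default). Instead of `beta`, a target `signal_fraction` f may be given;
#' `beta` is then derived at generation time as
#' `sqrt(f / (1 - f) * (sigma^2 + patient_sd^2))`, i.e. f is the share of
#' row-level feature variance carried by the pathway signal.
#'
#' @param set Gene-set name (or index into the generated collection).
#' @param features Integer feature indices (1-based) to couple.
#' @param beta Linear effect size; ignored when `signal_fraction` is given.
#' @param sigma Residual SD of the coupled feature.
#' @param signal_fraction Optional target signal-variance fraction in (0, 1).
#' @return A `coupling` list.
#' @export
coupling <- function(set, features, beta = 1, sigma = 1,
                     signal_fraction = NULL) {
  if (!is.null(signal_fraction)) {
    stopifnot(signal_fraction > 0, signal_fraction < 1)
  }
  structure(list(set = set, features = as.integer(features), beta = beta,
                 sigma = sigma, signal_fraction = signal_fraction),
            class = "coupling")
}

validate_cohort_config <- function(cfg) {
  with(cfg, {
    if (n_ctmvp > n_patients || n_net > n_patients || n_ed > n_patients) {
      abort("Zone patient counts cannot exceed `n_patients`.")
    }
    if (n_all_three > min(n_ed, n_net)) {
      abort("`n_all_three` cannot exceed the NET or ED patient counts.")
    }
    if (n_gene_sets * genes_per_set > n_genes) {
      abort("`n_gene_sets * genes_per_set` exceeds `n_genes`.")
    }
    n_structured <- n_nzv_features + n_corr_blocks * block_size
    if (n_structured > n_features) {
      abort("NZV features plus correlated-block features exceed `n_features`.")
    }
    if (within_block_rho < 0 || within_block_rho > 1) {
      abort("`within_block_rho` must be in [0, 1].")
    }
    planted <- unlist(lapply(couplings, `[[`, "features"))
    if (length(planted)) {
      if (any(planted < 1 | planted > n_features)) {
        abort("Planted feature indices must lie in [1, n_features].")
      }
      if (any(planted <= n_structured)) {
        abort("Planted features collide with NZV/correlated-block features.")
      }
    }
  })
  invisible(cfg)
}

zone_levels <- c("CT", "CTmvp", "CTpan", "IT", "LE")

# Seeded zone assignment honouring the configured fixed counts.
assign_zones <- function(cfg) {
  patients <- sprintf("P%03d", seq_len(cfg$n_patients))
  withr::with_seed(derive_seed(cfg$seed, "zones"), {
    net <- sample(patients, cfg$n_net)
    ed_in_net <- sample(net, cfg$n_all_three)
    ed_out <- sample(setdiff(patients, net), cfg$n_ed - cfg$n_all_three)
    ed <- c(ed_in_net, ed_out)
    ctmvp <- sample(patients, cfg$n_ctmvp)
    # every ED patient has an IT sample; every other one also LE
    le <- ed[seq_along(ed) %% 2 == 0]
  })
  list(patients = patients,
       zones = list(CT = patients, CTmvp = ctmvp, CTpan = net,
                    IT = ed, LE = le))
}

#' Generate a synthetic radiogenomic cohort
#'
#' Expression is generated on the log2 scale (per-gene Gaussian baselines,
#' set-coherent zone shifts, per-patient pathway activity for genes in a
#' set) and back-transformed to FPKM via `pmax(2^x - 1, 0)`, so that the
#' `log2(FPKM + 1)` transform used by the scorer recovers the generative
#' scale. Radiomic features are row-level Gaussians around a per-patient
#' random intercept, with near-zero-variance columns, correlated blocks,
#' and the planted couplings declared in the configuration.
#'
#' @param config A [cohort_config()].
#' @return An object of class `rg_cohort`: a list with tibbles
#'   `expression` (wide, `gene_id` + samples), `samples` (`sample_id`,
#'   `patient_id`, `zone`), `gene_sets`, `radiomics`
#'   (`patient_id`, `subcompartment`, `feat_*`), `covariates`, and a
#'   `truth` list recording couplings, latent activities and patient
#'   intercepts.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_genes = 100, n_gene_sets = 4,
#'                                         n_features = 20, seed = 1))
#' nrow(cohort$radiomics)  # 50 rows: ET 28 + NET 15 + ED 7
#' @export
generate_cohort <- function(config) {
  cfg <- if (inherits(config, "cohort_config")) config else
    do.call(cohort_config, config)
  az <- assign_zones(cfg)
  patients <- az$patients

  samples <- purrr::imap_dfr(az$zones, function(pts, zone) {
    tibble(patient_id = pts, zone = zone)
  }) |>
    mutate(sample_id = paste(.data$patient_id, .data$zone, sep = "_")) |>
    arrange(.data$patient_id, factor(.data$zone, levels = zone_levels)) |>
    select("sample_id", "patient_id", "zone")

  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  categories <- rep("custom", cfg$n_gene_sets)
  if (cfg$n_gene_sets == 24) {
    categories <- rep(c("hallmark", "neftel", "ivygap_module"), c(15, 4, 5))
  } else {
    categories <- rep("hallmark", cfg$n_gene_sets)
  }
  set_names <- sprintf("SET_%02d", seq_len(cfg$n_gene_sets))
  gene_sets <- tibble(
    set_name = set_names,
    category = categories,
    genes = lapply(seq_len(cfg$n_gene_sets), function(s) {
      gene_ids[((s - 1) * cfg$genes_per_set + 1):(s * cfg$genes_per_set)]
    })
  )

  # latent structure
  zone_shift <- withr::with_seed(derive_seed(cfg$seed, "zoneprofile"), {
    matrix(rnorm(cfg$n_gene_sets * 5, 0, cfg$zone_profile_sd),
           nrow = cfg$n_gene_sets, dimnames = list(set_names, zone_levels))
  })
  activity <- withr::with_seed(derive_seed(cfg$seed, "activity"), {
    matrix(rnorm(cfg$n_patients * cfg$n_gene_sets, 0, cfg$activity_sd),
           nrow = cfg$n_patients, dimnames = list(patients, set_names))
  })

  # expression on log2 scale
  n_samp <- nrow(samples)
  base <- withr::with_seed(derive_seed(cfg$seed, "genebase"),
                           rnorm(cfg$n_genes, cfg$gene_base_mean,
                                 cfg$gene_base_sd))
  log_expr <- matrix(base, nrow = cfg$n_genes, ncol = n_samp) +
    withr::with_seed(derive_seed(cfg$seed, "exprnoise"),
                     matrix(rnorm(cfg$n_genes * n_samp, 0,
                                  cfg$expression_noise_sd),
                            nrow = cfg$n_genes))
  rownames(log_expr) <- gene_ids
  colnames(log_expr) <- samples$sample_id
  gene_set_of <- rep(NA_integer_, cfg$n_genes)
  for (s in seq_len(cfg$n_gene_sets)) {
    gene_set_of[((s - 1) * cfg$genes_per_set + 1):(s * cfg$genes_per_set)] <- s
  }
  in_set <- !is.na(gene_set_of)
  shift <- zone_shift[gene_set_of[in_set], samples$zone, drop = FALSE] +
    t(activity[samples$patient_id, gene_set_of[in_set], drop = FALSE])
  log_expr[in_set, ] <- log_expr[in_set, ] + shift

  fpkm <- pmax(2^log_expr - 1, 0)
  expression <- bind_cols(tibble(gene_id = gene_ids),
                          as_tibble(fpkm, .name_repair = "minimal"))

  # radiomic table: one row per patient x available subcompartment
  pmap <- primary_zone_map()
  avail <- samples |>
    mutate(subcompartment = unname(pmap$mapping[.data$zone])) |>
    distinct(.data$patient_id, .data$subcompartment)
  n_rows <- nrow(avail)
  intercepts <- withr::with_seed(derive_seed(cfg$seed, "patient_intercepts"),
                                 setNames(rnorm(cfg$n_patients, 0,
                                                cfg$patient_sd), patients))
  u <- intercepts[avail$patient_id]

  feat_names <- sprintf("feat_%04d", seq_len(cfg$n_features))
  X <- withr::with_seed(derive_seed(cfg$seed, "featnoise"),
                        matrix(rnorm(n_rows * cfg$n_features),
                               nrow = n_rows)) + u
  colnames(X) <- feat_names

  idx <- 0
  nzv_idx <- integer(0)
  if (cfg$n_nzv_features > 0) {
    nzv_idx <- idx + seq_len(cfg$n_nzv_features)
    X[, nzv_idx] <- withr::with_seed(derive_seed(cfg$seed, "nzv"), {
      vapply(nzv_idx, function(j) {
        v <- rep(0, n_rows)
        n_var <- max(1, floor(n_rows * (1 - cfg$nzv_fraction)))
        v[sample(n_rows, n_var)] <- sample(1:3, n_var, replace = TRUE)
        v
      }, numeric(n_rows))
    })
    idx <- idx + cfg$n_nzv_features
  }
  block_idx <- list()
  if (cfg$n_corr_blocks > 0) {
    s_noise <- sqrt(max(1 / cfg$within_block_rho - 1, 0))
    X[, idx + seq_len(cfg$n_corr_blocks * cfg$block_size)] <-
      withr::with_seed(derive_seed(cfg$seed, "blocks"), {
        out <- matrix(0, n_rows, cfg$n_corr_blocks * cfg$block_size)
        for (b in seq_len(cfg$n_corr_blocks)) {
          z <- rnorm(n_rows)
          for (k in seq_len(cfg$block_size)) {
            out[, (b - 1) * cfg$block_size + k] <- z + s_noise * rnorm(n_rows)
          }
        }
        out
      })
    block_idx <- lapply(seq_len(cfg$n_corr_blocks), function(b) {
      idx + (b - 1) * cfg$block_size + seq_len(cfg$block_size)
    })
    idx <- idx + cfg$n_corr_blocks * cfg$block_size
  }

  truth_couplings <- purrr::imap_dfr(cfg$couplings, function(cp, i) {
    set_nm <- if (is.numeric(cp$set)) set_names[cp$set] else cp$set
    beta <- cp$beta
    if (!is.null(cp$signal_fraction)) {
      f <- cp$signal_fraction
      beta <- sqrt(f / (1 - f) * (cp$sigma^2 + cfg$patient_sd^2)) /
        cfg$activity_sd
    }
    a <- activity[avail$patient_id, set_nm]
    for (j in cp$features) {
      X[, j] <<- beta * a + u +
        withr::with_seed(derive_seed(cfg$seed, "coupling", i, j),
                         rnorm(n_rows, 0, cp$sigma))
    }
    tibble(set_name = set_nm, feature = feat_names[cp$features],
           beta = beta, sigma = cp$sigma)
  })

  radiomics <- bind_cols(avail, as_tibble(X, .name_repair = "minimal")) |>
    arrange(.data$patient_id,
            factor(.data$subcompartment, levels = c("ET", "NET", "ED")))

  covariates <- withr::with_seed(derive_seed(cfg$seed, "covariates"), {
    age <- rnorm(cfg$n_patients, cfg$age_mean, cfg$age_sd)
    while (any(bad <- age < 30 | age > 85)) {
      age[bad] <- rnorm(sum(bad), cfg$age_mean, cfg$age_sd)
    }
    tibble(
      patient_id = patients,
      age = round(age, 1),
      mgmt_methylated = rbinom(cfg$n_patients, 1, cfg$mgmt_prob),
      subtype = sample(c("Classical", "Mesenchymal", "Proneural"),
                       cfg$n_patients, replace = TRUE)
    )
  })

  structure(
    list(expression = expression, samples = samples, gene_sets = gene_sets,
         radiomics = radiomics, covariates = covariates,
         truth = list(couplings = truth_couplings,
                      activity = activity,
                      patient_intercepts = intercepts,
                      zone_shift = zone_shift,
                      nzv_features = feat_names[nzv_idx],
                      corr_blocks = lapply(block_idx, function(ii)
                        feat_names[ii])),
         config = cfg),
    class = "rg_cohort"
  )
}

#' @export
print.rg_cohort <- function(x, ...) {
  cat(sprintf(
    "<rg_cohort> %d patients, %d zone samples, %d genes, %d gene sets, %d features\n",
    x$config$n_patients, nrow(x$samples), x$config$n_genes,
    x$config$n_gene_sets, x$config$n_features))
  cat(sprintf("  radiomic rows: %d (%s)\n", nrow(x$radiomics),
              paste(sprintf("%s=%d", names(table(x$radiomics$subcompartment)),
                            table(x$radiomics$subcompartment)),
                    collapse = ", ")))
  cat(sprintf("  planted couplings: %d\n", nrow(x$truth$couplings)))
  invisible(x)
}

#' Write a cohort to plain-text fixture files
#'
#' Emits `expression.tsv`, `samples.csv`, `gene_sets.gmt`, `radiomics.csv`,
#' `covariates.csv` and `truth.json` into `dir`. All tables round-trip
#' losslessly through [read_cohort()].
#'
#' @param cohort An `rg_cohort`.
#' @param dir Writable directory (created if missing).
#' @return A manifest tibble (`file`, `path`, `n_rows`), invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    samples = file.path(dir, "samples.csv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    radiomics = file.path(dir, "radiomics.csv"),
    covariates = file.path(dir, "covariates.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_expression_tsv(cohort$expression, paths$expression)
  readr::write_csv(cohort$samples, paths$samples)
  write_gmt(cohort$gene_sets, paths$gene_sets)
  readr::write_csv(cohort$radiomics, paths$radiomics)
  readr::write_csv(cohort$covariates, paths$covariates)
  jsonlite::write_json(
    list(couplings = cohort$truth$couplings,
         patient_intercepts = as.list(cohort$truth$patient_intercepts),
         nzv_features = cohort$truth$nzv_features,
         corr_blocks = cohort$truth$corr_blocks,
         seed = cohort$config$seed),
    paths$truth, digits = NA, auto_unbox = TRUE)
  manifest <- tibble(
    file = names(paths), path = unlist(paths),
    n_rows = c(nrow(cohort$expression), nrow(cohort$samples),
               nrow(cohort$gene_sets), nrow(cohort$radiomics),
               nrow(cohort$covariates), NA_integer_)
  )
  invisible(manifest)
}

#' Read a cohort fixture directory written by [write_cohort()]
#'
#' @param dir Directory containing the fixture files.
#' @return A list with `expression`, `samples`, `gene_sets`, `radiomics`,
#'   `covariates` (and `truth` when present).
#' @export
read_cohort <- function(dir) {
  out <- list(
    expression = read_expression_tsv(file.path(dir, "expression.tsv")),
    samples = readr::read_csv(file.path(dir, "samples.csv"),
                              show_col_types = FALSE, progress = FALSE),
    gene_sets = read_gmt(file.path(dir, "gene_sets.gmt")),
    radiomics = readr::read_csv(file.path(dir, "radiomics.csv"),
                                show_col_types = FALSE, progress = FALSE),
    covariates = readr::read_csv(file.path(dir, "covariates.csv"),
                                 show_col_types = FALSE, progress = FALSE)
  )
  truth_path <- file.path(dir, "truth.json")
  if (file.exists(truth_path)) {
    out$truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
  }
  out
}
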