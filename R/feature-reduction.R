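# Three-stage radiomic feature reduction: near-zero-variance filter,
# deterministic correlation pruning, and the supervised univariate
# Spearman screen (full-data mode for the mixed-model analysis; in-fold
# mode for nested cross-validation).

#' Near-zero-variance filter
#'
#' Drops features that are constant, or whose frequency ratio (count of the
#' most common value over the count of the second most common) exceeds
#' `freq_ratio_cut` while their percentage of distinct values is below
#' `unique_pct_cut`. Delegates to `caret::nearZeroVar()`, whose defaults
#' (95/5 and 10) are adopted.
#'
#' @param radiomics Radiomic table (`patient_id`, `subcompartment`,
#'   feature columns).
#' @param freq_ratio_cut Frequency-ratio cutoff (default 95/5 = 19).
#' @param unique_pct_cut Percent-unique cutoff (default 10).
#' @return The filtered table; dropped feature ids are recorded in the
#'   `reduction_stages` attribute (see [reduction_stages()]).
#' @export
near_zero_variance_filter <- function(radiomics, freq_ratio_cut = 95 / 5,
                                      unique_pct_cut = 10) {
  feats <- feature_columns(radiomics)
  if (nrow(radiomics) < 2) abort("Need >= 2 rows.")
  drop_idx <- caret::nearZeroVar(radiomics[feats], freqCut = freq_ratio_cut,
                                 uniqueCut = unique_pct_cut)
  dropped <- feats[drop_idx]
  out <- radiomics[setdiff(names(radiomics), dropped)]
  add_stage(out, radiomics, stage = "near_zero_variance", dropped = dropped)
}

#' Deterministic pairwise correlation pruning
#'
#' While any pair of retained features has absolute Spearman correlation
#' above `rho_cut`, the member of the worst-offending pair with the larger
#' mean absolute correlation to all currently retained features is dropped
#' (ties broken by dropping the lexicographically larger feature id).
#' Survivors have all pairwise |rho| <= `rho_cut`. Unlike the common
#' greedy heuristic this rule does not depend on column order.
#'
#' @param radiomics Radiomic table.
#' @param rho_cut Absolute Spearman correlation threshold (default 0.90).
#' @return The pruned table, with stage annotation.
#' @export
correlation_prune <- function(radiomics, rho_cut = 0.90) {
  feats <- feature_columns(radiomics)
  if (nrow(radiomics) < 3) abort("Need >= 3 rows.")
  X <- as.matrix(radiomics[feats])
  C <- abs(suppressWarnings(cor(X, method = "spearman")))
  C[!is.finite(C)] <- 0
  diag(C) <- 0
  keep <- feats
  repeat {
    sub <- C[keep, keep, drop = FALSE]
    if (!length(sub) || max(sub) <= rho_cut) break
    worst <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    a <- keep[worst[["row"]]]; b <- keep[worst[["col"]]]
    mean_a <- mean(sub[a, ]); mean_b <- mean(sub[b, ])
    drop_one <- if (mean_a > mean_b) a
    else if (mean_b > mean_a) b
    else max(a, b)
    keep <- setdiff(keep, drop_one)
  }
  out <- radiomics[c(setdiff(names(radiomics), feats), keep)]
  add_stage(out, radiomics, stage = "correlation_prune",
            dropped = setdiff(feats, keep))
}

add_stage <- function(out, input, stage, dropped) {
  stages <- attr(input, "reduction_stages") %||% list()
  stages[[stage]] <- list(n_before = length(feature_columns(input)),
                          n_after = length(feature_columns(out)),
                          dropped = dropped)
  attr(out, "reduction_stages") <- stages
  out
}

#' Stage report of a reduced radiomic table
#'
#' @param radiomics A table that has passed through the reduction filters.
#' @return A tibble (`stage`, `n_before`, `n_after`, `n_dropped`).
#' @export
reduction_stages <- function(radiomics) {
  stages <- attr(radiomics, "reduction_stages") %||% list()
  purrr::imap_dfr(stages, function(s, nm) {
    tibble(stage = nm, n_before = s$n_before, n_after = s$n_after,
           n_dropped = length(s$dropped))
  })
}

# Selection core shared by univariate_screen() and the in-fold screening
# of the nested CV loop: BH across features, min-FDR gate, rank by raw p
# (ties by feature id), cap.
screen_select <- function(X, y, fdr_cut, cap) {
  st <- screen_stats_one_group(X, y)
  fdr <- p.adjust(st$p, method = "BH")
  eligible <- which(!is.na(fdr) & fdr < fdr_cut)
  ord <- eligible[order(st$p[eligible], colnames(X)[eligible])]
  colnames(X)[head(ord, cap)]
}

# Per-feature Spearman rho and p against y; exact p for n <= 9 without
# ties, tie-corrected t approximation otherwise.
screen_stats_one_group <- function(X, y) {
  n <- length(y)
  if (n <= 9) {
    res <- apply(X, 2, function(x) {
      st <- spearman_test(x, y)
      c(st$rho, st$p)
    })
    list(rho = res[1, ], p = res[2, ])
  } else {
    spearman_screen_stats(X, y)
  }
}

#' Supervised univariate Spearman screen
#'
#' Per feature, Spearman correlation with the pathway score. In
#' `per_subcompartment` mode the correlation and a Benjamini-Hochberg FDR
#' are computed within each subcompartment separately (subcompartments
#' with fewer than `min_rows` rows are skipped) and a feature is eligible
#' when its minimum FDR across subcompartments is below `fdr_cut`. In
#' `patient_level` mode the table must hold one row per patient and a
#' single FDR is computed across features. Eligible features are ranked by
#' minimum raw p (ties by feature id) and truncated at `cap`. An empty
#' selection is a valid outcome (the pathway gets no features).
#'
#' @param radiomics Radiomic table (for `patient_level` mode: one row per
#'   patient with a `score` outcome column or `scores` supplied).
#' @param scores For `per_subcompartment` mode, the observation table of
#'   [aggregate_to_subcompartments()]; for `patient_level` mode, a tibble
#'   with `patient_id` and `score`.
#' @param set_name Gene set whose scores are screened against (ignored if
#'   `scores` already holds a single set).
#' @param mode `"per_subcompartment"` or `"patient_level"`.
#' @param fdr_cut FDR eligibility threshold (default 0.10).
#' @param cap Maximum number of selected features (default 5).
#' @param min_rows Minimum rows per tested subcompartment (default 4).
#' @return An `rg_screen` object: list with `table` (long per feature x
#'   group stats), `summary` (per feature min FDR / min p / selection),
#'   `selected` (ordered character vector), and the screening settings.
#' @export
univariate_screen <- function(radiomics, scores, set_name = NULL,
                              mode = c("per_subcompartment", "patient_level"),
                              fdr_cut = 0.10, cap = 5, min_rows = 4) {
  mode <- match.arg(mode)
  feats <- feature_columns(radiomics)
  if (!is.null(set_name)) {
    scores <- scores |> filter(.data$set_name == !!set_name)
  }
  if (mode == "per_subcompartment") {
    d <- inner_join(radiomics, scores |>
                      select("patient_id", "subcompartment", "score"),
                    by = c("patient_id", "subcompartment"))
    groups <- split(d, d$subcompartment)
  } else {
    d <- inner_join(radiomics, scores |> select("patient_id", "score"),
                    by = "patient_id")
    if (anyDuplicated(d$patient_id)) {
      abort("patient_level screening expects one row per patient.")
    }
    groups <- list(all = d)
  }
  long <- purrr::imap_dfr(groups, function(g, nm) {
    if (nrow(g) < min_rows) return(tibble())
    st <- screen_stats_one_group(as.matrix(g[feats]), g$score)
    tibble(feature = feats, group = nm, rho = st$rho, p = st$p,
           fdr = p.adjust(st$p, method = "BH"))
  })
  if (!nrow(long)) abort("No screenable group had enough rows.")
  summary <- long |>
    summarise(min_fdr = suppressWarnings(min(.data$fdr, na.rm = TRUE)),
              min_p = suppressWarnings(min(.data$p, na.rm = TRUE)),
              .by = "feature") |>
    mutate(min_fdr = ifelse(is.finite(.data$min_fdr), .data$min_fdr, NA),
           min_p = ifelse(is.finite(.data$min_p), .data$min_p, NA),
           eligible = !is.na(.data$min_fdr) & .data$min_fdr < fdr_cut) |>
    arrange(.data$min_p, .data$feature)
  selected <- head(summary$feature[summary$eligible], cap)
  summary$selected <- summary$feature %in% selected
  structure(list(table = long, summary = summary, selected = selected,
                 set_name = set_name, mode = mode, fdr_cut = fdr_cut,
                 cap = cap),
            class = "rg_screen")
}

#' @export
print.rg_screen <- function(x, ...) {
  cat(sprintf("<rg_screen> mode=%s fdr<%.2g cap=%d: %d selected\n",
              x$mode, x$fdr_cut, x$cap, length(x$selected)))
  if (length(x$selected)) cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
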