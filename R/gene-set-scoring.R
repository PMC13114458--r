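# Single-sample gene-set enrichment scoring of FPKM expression,
# zone-module derivation by per-gene Wilcoxon differential expression,
# and gene-set overlap (Jaccard) diagnostics.

#' log2(FPKM + 1) transform of a wide expression table
#'
#' @param expression Wide expression tibble (`gene_id` + sample columns),
#'   values >= 0.
#' @return The same tibble with every value replaced by `log2(x + 1)`.
#' @export
log2_fpkm <- function(expression) {
  validate_expression(expression)
  samp <- setdiff(names(expression), "gene_id")
  expression[samp] <- log2(as.matrix(expression[samp]) + 1)
  expression
}

# Per-gene Gaussian-kernel CDF transform across samples (bandwidth sd/4;
# constant genes map to 0.5). Monotone per gene, but reorders genes within
# a sample, which is why it is exposed as a flag.
kernel_cdf_transform <- function(mat) {
  t(apply(mat, 1, function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) return(rep(0.5, length(x)))
    h <- s / 4
    colMeans(pnorm(outer(x, x, "-") / -h))
  }))
}

#' Single-sample gene-set enrichment scores
#'
#' For each sample, genes are ranked in decreasing order of the per-sample
#' statistic (log2(FPKM+1), optionally passed through a per-gene Gaussian
#' kernel CDF across samples first). Walking down the ranking, the score of
#' a set is the sum over all rank positions of the weighted cumulative
#' in-set fraction minus the unweighted cumulative out-of-set fraction.
#' In-set weights are `rank^weight_exponent`, where `rank` is the
#' descending-rank statistic (`n_genes` for the top gene down to 1), so
#' that with the kernel transform off the score is a pure rank statistic,
#' invariant to any strictly monotone per-sample transform of expression.
#' Ties are broken stably by gene id.
#'
#' @param expression Wide FPKM expression tibble (`gene_id` + samples).
#' @param gene_sets Gene-set tibble (see [read_gmt()]).
#' @param samples Optional sample metadata (`sample_id`, `patient_id`,
#'   `zone`) joined onto the result.
#' @param weight_exponent Non-negative weighting exponent (0 = unweighted;
#'   default 0.25, the usual single-sample enrichment convention).
#' @param kernel_transform Apply the per-gene Gaussian kernel CDF across
#'   samples before ranking (default `TRUE`).
#' @param normalize Divide all scores by the (max - min) over the whole
#'   table (default `TRUE`). Downstream z-scoring makes the analysis
#'   invariant to this within a pathway.
#' @param log_transform Apply `log2(x + 1)` first (default `TRUE`; set to
#'   `FALSE` if the input is already log-scale).
#' @return A long tibble (`sample_id`, `set_name`, `score`), plus metadata
#'   columns when `samples` is supplied. Sets whose genes are entirely
#'   absent from the expression table are skipped with a warning; absent
#'   genes of partially covered sets are dropped with a warning.
#' @examples
#' expr <- tibble::tibble(gene_id = c("g1", "g2", "g3"), s1 = c(8, 4, 2))
#' sets <- tibble::tibble(set_name = "up", category = "custom",
#'                        genes = list("g1"))
#' ssgsea_scores(expr, sets, weight_exponent = 0, kernel_transform = FALSE,
#'               normalize = FALSE)$score  # 1.5
#' @export
ssgsea_scores <- function(expression, gene_sets, samples = NULL,
                          weight_exponent = 0.25, kernel_transform = TRUE,
                          normalize = TRUE, log_transform = TRUE) {
  validate_gene_sets(gene_sets, min_size = 1)
  if (log_transform) expression <- log2_fpkm(expression)
  samp_cols <- setdiff(names(expression), "gene_id")
  mat <- as.matrix(expression[samp_cols])
  rownames(mat) <- expression$gene_id
  if (length(samp_cols) < 1) abort("Expression table has no samples.")

  present <- lapply(gene_sets$genes, function(g) g[g %in% expression$gene_id])
  missing_n <- lengths(gene_sets$genes) - lengths(present)
  if (any(missing_n > 0 & lengths(present) > 0)) {
    warn(sprintf("Dropped %d absent gene(s) across %d set(s).",
                 sum(missing_n), sum(missing_n > 0 & lengths(present) > 0)))
  }
  empty <- lengths(present) == 0
  if (any(empty)) {
    warn(sprintf("Skipping set(s) with no genes in the expression table: %s",
                 paste(gene_sets$set_name[empty], collapse = ", ")))
  }
  keep_sets <- which(!empty)
  if (!length(keep_sets)) abort("No gene set overlaps the expression table.")

  if (kernel_transform) mat <- kernel_cdf_transform(mat)

  n_genes <- nrow(mat)
  gene_ids <- expression$gene_id
  member <- vapply(present[keep_sets], function(g) gene_ids %in% g,
                   logical(n_genes))

  score_one <- function(x) {
    ord <- order(-x, gene_ids)
    rank_stat <- n_genes:1L
    w <- rank_stat^weight_exponent
    ind <- member[ord, , drop = FALSE]
    vapply(seq_len(ncol(ind)), function(k) {
      ink <- ind[, k]
      denom_in <- sum(w[ink])
      p_in <- if (denom_in > 0) cumsum(w * ink) / denom_in else
        cumsum(ink) / sum(ink)
      n_out <- n_genes - sum(ink)
      p_out <- if (n_out > 0) cumsum(!ink) / n_out else rep(0, n_genes)
      sum(p_in - p_out)
    }, numeric(1))
  }

  sc <- apply(mat, 2, score_one)
  if (is.null(dim(sc))) sc <- matrix(sc, nrow = 1)
  rownames(sc) <- gene_sets$set_name[keep_sets]
  if (normalize) {
    rng <- max(sc) - min(sc)
    if (rng > 0) sc <- sc / rng
  }
  out <- as_tibble(expand.grid(set_name = rownames(sc),
                               sample_id = colnames(mat),
                               stringsAsFactors = FALSE)) |>
    mutate(score = as.numeric(sc)) |>
    select("sample_id", "set_name", "score")
  if (!is.null(samples)) {
    out <- left_join(out, samples, by = "sample_id") |>
      select("sample_id", "patient_id", "zone", "set_name", "score")
  }
  out
}

# Vectorised two-sided Wilcoxon rank-sum p (normal approximation with tie
# correction and continuity correction, as stats::wilcox.test uses for
# non-exact cases) for every row of `mat` comparing columns in `grp` vs out.
wilcoxon_rows <- function(mat, grp) {
  n1 <- sum(grp); n2 <- sum(!grp); n <- n1 + n2
  apply(mat, 1, function(x) {
    r <- rank(x)
    W <- sum(r[grp]) - n1 * (n1 + 1) / 2
    ties <- table(x)
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- W - n1 * n2 / 2
    z <- sign(z) * max(0, abs(z) - 0.5)  # continuity correction
    2 * pnorm(-abs(z) / sqrt(sigma2))
  })
}

#' Derive zone-specific gene modules by differential expression
#'
#' For each zone, every gene is tested with a two-sided Wilcoxon rank-sum
#' test of log2(FPKM+1) in-zone versus all other zones; p-values are
#' BH-adjusted across genes within the zone. Genes with FDR below
#' `fdr_cut` and an absolute difference of mean log2(FPKM+1) above
#' `lfc_cut` are retained, ranked by ascending FDR (ties: descending
#' absolute difference, then gene id), and truncated at `top_k`.
#'
#' @param expression Wide FPKM expression tibble.
#' @param samples Sample metadata with `sample_id` and `zone`.
#' @param top_k Maximum module size (default 200).
#' @param fdr_cut,lfc_cut Retention filters (defaults 0.05 and 1).
#' @return A gene-set tibble (category `ivygap_module`, set names
#'   `module_<zone>`); zones with fewer than 2 samples are skipped with a
#'   warning, and zones with no passing genes are omitted.
#' @export
derive_zone_modules <- function(expression, samples, top_k = 200,
                                fdr_cut = 0.05, lfc_cut = 1) {
  lg <- log2_fpkm(expression)
  samp_cols <- intersect(names(lg), samples$sample_id)
  if (length(unique(samples$zone[samples$sample_id %in% samp_cols])) < 2) {
    abort("Need >= 2 zones to derive zone modules.")
  }
  mat <- as.matrix(lg[samp_cols])
  rownames(mat) <- lg$gene_id
  zone_of <- setNames(samples$zone, samples$sample_id)[samp_cols]

  mods <- purrr::map_dfr(unique(zone_of), function(z) {
    grp <- zone_of == z
    if (sum(grp) < 2) {
      warn(sprintf("Zone %s has < 2 samples; skipped.", z))
      return(tibble())
    }
    p <- wilcoxon_rows(mat, grp)
    fdr <- p.adjust(p, method = "BH")
    delta <- rowMeans(mat[, grp, drop = FALSE]) -
      rowMeans(mat[, !grp, drop = FALSE])
    keep <- which(fdr < fdr_cut & abs(delta) > lfc_cut)
    if (!length(keep)) return(tibble())
    ord <- keep[order(fdr[keep], -abs(delta[keep]), rownames(mat)[keep])]
    ord <- head(ord, top_k)
    tibble(set_name = paste0("module_", z), category = "ivygap_module",
           genes = list(rownames(mat)[ord]))
  })
  mods
}

#' Pairwise Jaccard similarity of gene sets
#'
#' `J(A, B) = |A intersect B| / |A union B|`; the diagonal is 1.
#'
#' @param gene_sets Gene-set tibble with >= 2 sets.
#' @return A symmetric numeric matrix with set names as dimnames.
#' @export
jaccard_matrix <- function(gene_sets) {
  validate_gene_sets(gene_sets)
  if (nrow(gene_sets) < 2) abort("Need >= 2 gene sets.")
  n <- nrow(gene_sets)
  J <- matrix(1, n, n,
              dimnames = list(gene_sets$set_name, gene_sets$set_name))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- gene_sets$genes[[i]]; b <- gene_sets$genes[[j]]
      J[i, j] <- J[j, i] <-
        length(intersect(a, b)) / length(union(a, b))
    }
  }
  J
}
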