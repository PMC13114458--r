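# Shared internal helpers: hierarchical seeds, Spearman inference, validation.

#' Derive a child seed from a run seed and a context label
#'
#' All stochastic steps in the package draw their seed from one integer run
#' seed plus a textual context (e.g. `"radiomics"`, `"perm", i`), so that any
#' component can be regenerated in isolation without replaying the whole run.
#' The derivation is a small deterministic integer hash kept below 2^31.
#'
#' @param seed Integer run seed.
#' @param ... Character or numeric context labels.
#' @return A single integer seed.
#' @keywords internal
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  label <- paste(c(...), collapse = ":")
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Spearman correlation with a reproducible p-value
#'
#' Computes Spearman's rho on midranks and a two-sided p-value from the
#' t approximation `t = rho * sqrt((n-2)/(1-rho^2))` (valid under ties);
#' for n <= 9 without ties the exact permutation distribution is used.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A list with elements `rho`, `p`, `n`.
#' @keywords internal
spearman_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4 || sd(x) == 0 || sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- cor(rank(x), rank(y))
  if (n <= 9 && !anyDuplicated(x) && !anyDuplicated(y)) {
    p <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
    )
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = min(1, p), n = n)
}

# Vectorised Spearman rho + t-approximation p of each column of X against y.
spearman_screen_stats <- function(X, y) {
  n <- length(y)
  ry <- rank(y)
  rx <- apply(X, 2, rank)
  rho <- suppressWarnings(as.numeric(cor(rx, ry)))
  rho[!is.finite(rho)] <- NA_real_
  p <- rep(NA_real_, length(rho))
  fin <- is.finite(rho)
  r <- pmin(pmax(rho[fin], -1 + 1e-12), 1 - 1e-12)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p[fin] <- 2 * pt(-abs(tstat), df = n - 2)
  list(rho = rho, p = p)
}

assert_prob <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be numeric in [0, 1].", what))
  }
  invisible(x)
}

#' Hash of the semantic content of a configuration
#'
#' @param x Any R object (typically a run configuration list).
#' @return A character md5 digest.
#' @keywords internal
config_hash <- function(x) rlang::hash(x)
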