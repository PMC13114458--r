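# ggplot2 displays for the main result types.

#' Observed-versus-predicted plot for a nested CV result
#'
#' @param object An `rg_nestedcv`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.rg_nestedcv <- function(object, ...) {
  ggplot(object$predictions, aes(x = .data$y, y = .data$yhat)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2,
                colour = "grey60") +
    geom_point() +
    labs(x = "Observed pathway score (z)",
         y = "Held-out prediction",
         title = object$set_name,
         subtitle = sprintf("R2cv = %.3f, MAE = %.3f, rho = %.3f",
                            object$r2_cv, object$mae,
                            object$spearman_rho)) +
    theme_minimal()
}

#' Null-distribution plot for a permutation test
#'
#' @param object An `rg_perm`.
#' @param statistic Which statistic to show (default the first).
#' @param ... Unused.
#' @return A ggplot: null histogram with the observed value marked.
#' @exportS3Method ggplot2::autoplot
autoplot.rg_perm <- function(object, statistic = names(object$observed)[1],
                             ...) {
  d <- tibble(value = object$null[[statistic]])
  ggplot(d, aes(x = .data$value)) +
    geom_histogram(bins = 30, fill = "grey75", colour = "white") +
    geom_vline(xintercept = object$observed[[statistic]],
               colour = "firebrick", linewidth = 1) +
    labs(x = statistic, y = "Permutations",
         title = sprintf("%s permutation null (N = %d)",
                         object$framework, object$n_perm),
         subtitle = sprintf("p = %.4g", object$p[[statistic]])) +
    theme_minimal()
}

#' Forest plot of nested CV performance across gene sets
#'
#' @param cv_table The `cv_table` of an `rg_study` (or any tibble with
#'   `set_name`, `r2_cv`, `ci_low`, `ci_high`, optionally `category`).
#' @return A ggplot ordered by descending R2cv with bootstrap intervals.
#' @export
plot_cv_summary <- function(cv_table) {
  d <- cv_table |>
    mutate(set_name = stats::reorder(.data$set_name, .data$r2_cv))
  p <- ggplot(d, aes(x = .data$r2_cv, y = .data$set_name))
  if ("category" %in% names(d)) p <- p + geom_point(aes(colour = .data$category))
  else p <- p + geom_point()
  p +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high),
                   height = 0.2, colour = "grey50") +
    geom_vline(xintercept = 0, linetype = 2) +
    labs(x = "Cross-validated R2 (LOPO)", y = NULL) +
    theme_minimal()
}

#' Feature-stability plot for a nested CV result
#'
#' @param x An `rg_nestedcv`.
#' @param min_fraction Show features selected in at least this fraction
#'   of folds (default 0.05).
#' @return A ggplot with the 50% stability threshold marked.
#' @export
plot_stability <- function(x, min_fraction = 0.05) {
  d <- x$stability |>
    filter(.data$fraction >= min_fraction) |>
    mutate(feature = stats::reorder(.data$feature, .data$fraction))
  ggplot(d, aes(x = .data$fraction, y = .data$feature)) +
    geom_point() +
    geom_vline(xintercept = 0.5, linetype = 2, colour = "firebrick") +
    scale_x_continuous(labels = function(v) sprintf("%.0f%%", 100 * v),
                       limits = c(0, 1)) +
    labs(x = "Folds selecting the feature", y = NULL,
         title = x$set_name) +
    theme_minimal()
}
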