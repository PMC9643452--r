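#' Plot held-out clock performance
#'
#' Observed versus predicted population doublings for the held-out test set
#' of a trained clock.
#'
#' @param object A `replitali_clock` with test pairs (see
#'   [train_replitali()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot replitali_clock
autoplot.replitali_clock <- function(object, ...) {
  if (is.null(object$test)) {
    fail("this clock carries no held-out test pairs to plot")
  }
  ggplot2::ggplot(object$test,
                  ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Observed PD (normalised)", y = "Estimated PD",
                  title = sprintf("Held-out clock performance (RMSE %.2f PD, R² %.3f)",
                                  object$metadata$test_rmse,
                                  object$metadata$test_r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot slope distributions across covariate bins
#'
#' @param object A `bin_comparison` (see [bin_and_compare()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot bin_comparison
autoplot.bin_comparison <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = factor(.data$bin), y = .data$slope)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.3, fill = "steelblue",
                          alpha = 0.5) +
    ggplot2::labs(x = sprintf("Covariate bin (1 = lowest of %d)", object$k),
                  y = expression(Delta * beta ~ "per PD"),
                  subtitle = sprintf("Kruskal-Wallis p = %.3g",
                                     object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot a median methylation trajectory against population doublings
#'
#' @param medians Output of [median_context_methylation()].
#' @param sample_pds Tibble (`sample_id`, `pd`) or named vector.
#' @param group Optional named vector (by sample id) used to colour points,
#'   e.g. lineage.
#' @return A ggplot.
#' @export
plot_median_methylation <- function(medians, sample_pds, group = NULL) {
  pds <- as_pd_vector(sample_pds, medians$sample_id)
  df <- dplyr::mutate(medians, pd = unname(pds))
  if (!is.null(group)) df$group <- group[df$sample_id]
  aes <- if (is.null(group)) {
    ggplot2::aes(x = .data$pd, y = .data$median_beta)
  } else {
    ggplot2::aes(x = .data$pd, y = .data$median_beta, colour = .data$group)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Population doublings",
                  y = "Median fractional methylation") +
    ggplot2::theme_minimal()
}
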