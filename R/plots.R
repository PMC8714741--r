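#' Plot a hierarchical regression report
#'
#' Forest plot of unstandardized coefficients with 95% confidence intervals,
#' faceted by block (the intercept is omitted).
#'
#' @param object A `hier_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hier_fit <- function(object, ...) {
  co <- tidy(object) %>%
    filter(.data$term != "(Intercept)") %>%
    mutate(
      lo = .data$B - 1.96 * .data$se_B,
      hi = .data$B + 1.96 * .data$se_B
    )
  ggplot2::ggplot(co, ggplot2::aes(x = .data$B, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$model), scales = "free_y", ncol = 1) +
    ggplot2::labs(
      x = "Unstandardized coefficient (95% CI)", y = NULL,
      title = paste("Hierarchical regression on", object$outcome)
    ) +
    ggplot2::theme_minimal()
}

#' Plot oblimin-rotated component loadings
#'
#' Heatmap of the pattern matrix; loadings below `cutoff` in absolute value
#' are left blank, mirroring how published loading tables are shown.
#'
#' @param object A `pca_oblimin` object.
#' @param cutoff Absolute loading below which cells are blanked (default
#'   0.3).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pca_oblimin <- function(object, cutoff = 0.3, ...) {
  long <- tidy(object) %>%
    mutate(
      measure = factor(.data$measure, levels = rev(rownames(object$pattern))),
      label = ifelse(abs(.data$loading) < cutoff, "",
        formatC(.data$loading, format = "f", digits = 2)
      )
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$component, y = .data$measure)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$loading), colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1.05, 1.05)) +
    ggplot2::labs(x = NULL, y = NULL, title = "Oblimin pattern loadings") +
    ggplot2::theme_minimal()
}

#' Plot cohort metric distributions
#'
#' Histograms of the fourteen behavioral measures of a scored cohort, useful
#' for eyeballing simulator calibration.
#'
#' @param metrics A metrics tibble from [score_cohort()].
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_metric_distributions <- function(metrics, bins = 20) {
  long <- metrics %>%
    select(any_of(metric_columns())) %>%
    pivot_longer(everything(), names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::facet_wrap(ggplot2::vars(.data$measure), scales = "free") +
    ggplot2::labs(x = NULL, y = "participants") +
    ggplot2::theme_minimal()
}
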