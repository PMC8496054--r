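# ggplot2 display functions for the main result types.

#' Plot n/c ratio against cell density
#'
#' Scatter of per-field nuclear/cytoplasmic ratios over nucleus counts with
#' the fitted regression line and the mean-count density threshold (dashed).
#'
#' @param x A `density_analysis` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.density_analysis <- function(x, ...) {
  df <- x$measurements[!is.na(x$measurements$nc_ratio), ]
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$nucleus_count, y = .data$nc_ratio
  )) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$density), alpha = 0.7) +
    ggplot2::geom_abline(
      slope = x$regression$slope, intercept = x$regression$intercept
    ) +
    ggplot2::geom_vline(xintercept = x$threshold, linetype = "dashed") +
    ggplot2::labs(
      x = "nuclei per field", y = "nuclear / cytoplasmic ratio",
      colour = "cell density"
    ) +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier curves
#'
#' Step curves of survival probability per group.
#'
#' @param x A `km_curve` object from [km_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.km_curve <- function(x, ...) {
  ggplot2::ggplot(tidy(x), ggplot2::aes(
    x = .data$time, y = .data$survival, colour = .data$group
  )) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability") +
    ggplot2::theme_minimal()
}

#' Heatmap of relative expression per gene and condition
#'
#' Tile display of a [condition_heatmap()] table (genes x conditions).
#'
#' @param heatmap Tibble from [condition_heatmap()].
#' @param fill_label Legend title.
#' @return A ggplot object.
#' @export
plot_condition_heatmap <- function(heatmap, fill_label = "RQ") {
  long <- heatmap |>
    tidyr::pivot_longer(
      -dplyr::any_of(c("gene", "annotation", "response_class")),
      names_to = "condition", values_to = "value"
    )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$condition, y = .data$gene, fill = .data$value
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "blue", mid = "white", high = "red", midpoint = 1,
      name = fill_label
    ) +
    ggplot2::theme_minimal()
}

#' Plot signature score distribution by group
#'
#' @param scores Tibble with `score` and a grouping column.
#' @param group Bare name of the grouping column (default `group`).
#' @return A ggplot object.
#' @export
plot_signature_scores <- function(scores, group = group) {
  ggplot2::ggplot(scores, ggplot2::aes(
    x = {{ group }}, y = .data$score
  )) +
    ggplot2::geom_violin() +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5) +
    ggplot2::labs(y = "signature score") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
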