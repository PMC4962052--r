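#' Spatiotemporal expression surface
#'
#' Mean relative expression per (segment, day) cell, drawn as a filled
#' tile surface over the ordered segment index and postnatal day --
#' presentational smoothing only, `interpolate = TRUE` passes bilinear
#' interpolation to the raster. Expression spans orders of magnitude, so
#' the fill is log10-scaled with a pseudo-count.
#'
#' @param samples A sample table (at least 2 segments and 2 days).
#' @param gene `"ghrelin"` or `"ghr"`.
#' @param interpolate Bilinear interpolation of the raster.
#' @return A ggplot object.
#' @export
plot_expression_surface <- function(samples, gene = c("ghrelin", "ghr"),
                                    interpolate = TRUE) {
  gene <- match.arg(gene)
  samples <- as_sample_table(samples)
  if (length(unique(samples$day)) < 2 || length(unique(samples$segment)) < 2) {
    abort("surface needs at least 2 days and 2 segments",
          class = "emma_design_error")
  }
  grid <- dplyr::summarise(
    dplyr::group_by(samples, .data$segment, .data$day),
    mean = mean(.data[[gene]]), .groups = "drop"
  )
  eps <- 1e-3
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$day,
                                     y = as.integer(.data$segment),
                                     fill = log10(.data$mean + eps))) +
    ggplot2::geom_raster(interpolate = interpolate) +
    ggplot2::scale_y_continuous(breaks = seq_along(git_segments()),
                                labels = git_segments(), trans = "reverse") +
    ggplot2::scale_fill_viridis_c(name = paste0("log10(", gene, ")")) +
    ggplot2::labs(x = "postnatal day", y = NULL,
                  title = paste("Spatiotemporal", gene, "expression")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.emma_comparison <- function(object, ...) {
  ggplot2::ggplot(object$means,
                  ggplot2::aes(x = .data$mean, y = stats::reorder(.data$method, -.data$mean))) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lower, xmax = .data$upper),
                            height = 0.2) +
    ggplot2::labs(x = "cross-validated RMSE",
                  y = NULL,
                  title = "Model comparison",
                  subtitle = sprintf("Bonferroni-adjusted %d%% confidence limits, %d pairs",
                                     round(100 * object$conf_level),
                                     object$n_pairs)) +
    ggplot2::theme_minimal()
}

#' Feature-importance bar chart
#'
#' @param importance Output of [feature_importance()], optionally with a
#'   `method` column for faceting.
#' @return A ggplot object.
#' @export
plot_importance <- function(importance) {
  p <- ggplot2::ggplot(importance,
                       ggplot2::aes(x = .data$importance,
                                    y = stats::reorder(.data$feature, .data$importance))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "importance (top = 100)", y = NULL) +
    ggplot2::theme_minimal()
  if ("method" %in% names(importance)) {
    p <- p + ggplot2::facet_wrap(~method)
  }
  p
}
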