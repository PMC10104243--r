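#' Density-colored scatter map
#'
#' Scatter of two record columns colored by the kernel density at each
#' point, the presentation used for distance-versus-angle maps.
#'
#' @param data record tibble.
#' @param x,y column names (strings).
#' @param bandwidth see [kde_at_points()].
#' @return a ggplot.
#' @export
plot_density_map <- function(data, x, y, bandwidth = NULL) {
  d <- kde_at_points(data, x, y, bandwidth = bandwidth)
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[x]], y = .data[[y]],
                                  color = .data$density)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.8) +
    ggplot2::scale_color_viridis_c(name = "kernel density") +
    ggplot2::theme_minimal()
}

#' Plot a normalized histogram record table
#'
#' Works for the pairwise-distance, anchored-angle, and proximity
#' histograms produced by the analysis functions (any table with
#' `bin_lo`, `bin_hi`, `probability`, optionally split by
#' `host_orientation_class`).
#'
#' @param hist histogram record tibble.
#' @param xlab x-axis label.
#' @return a ggplot.
#' @export
plot_histogram <- function(hist, xlab = "value") {
  p <- ggplot2::ggplot(hist, ggplot2::aes(
    x = (.data$bin_lo + .data$bin_hi) / 2,
    y = .data$probability,
    width = .data$bin_hi - .data$bin_lo
  )) +
    ggplot2::geom_col(fill = "steelblue", color = "grey30", linewidth = 0.2) +
    ggplot2::labs(x = xlab, y = "probability") +
    ggplot2::theme_minimal()
  if ("host_orientation_class" %in% names(hist)) {
    p <- p + ggplot2::facet_wrap(~host_orientation_class)
  }
  p
}

#' Plot a skeletonized meshwork
#'
#' @param stats a `skeleton_stats` object.
#' @return a ggplot of skeleton pixels.
#' @export
plot_skeleton <- function(stats) {
  px <- which(stats$skeleton, arr.ind = TRUE)
  d <- tibble(row = px[, 1], col = px[, 2])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = -.data$row)) +
    ggplot2::geom_tile(fill = "black") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("skeleton: %.0f nm, %d junctions",
                      stats$total_length, stats$n_junctions),
      x = NULL, y = NULL) +
    ggplot2::theme_void()
}
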