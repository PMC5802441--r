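#' Plot methods
#'
#' `autoplot()` methods give quick diagnostic figures for the main result
#' types; they return ggplot objects that can be themed further.
#'
#' @param object the object to plot.
#' @param ... unused.
#' @name gapscape-plots
NULL

#' @describeIn gapscape-plots score cloud of the fitted climate PCA,
#'   optionally with the equal-variance partition's breakpoint lines.
#' @param partition optional [equal_variance_breakpoints()] partition
#'   whose breakpoints are drawn as dashed lines.
#' @method autoplot climate_pca
#' @export
autoplot.climate_pca <- function(object, partition = NULL, ...) {
  p <- ggplot2::ggplot(object$scores, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4, colour = "grey40") +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained_fraction[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained_fraction[2])) +
    ggplot2::theme_minimal()
  if (!is.null(partition)) {
    p <- p +
      ggplot2::geom_vline(xintercept = partition$breakpoints$PC1,
                          linetype = "dashed", colour = "grey30") +
      ggplot2::geom_hline(yintercept = partition$breakpoints$PC2,
                          linetype = "dashed", colour = "grey30")
  }
  p
}

#' @describeIn gapscape-plots map of the climatic clusters (labelled
#'   partition).
#' @method autoplot climate_partition
#' @export
autoplot.climate_partition <- function(object, ...) {
  if (is.null(object$labels)) stop("partition has no labels; run assign_clusters()")
  ggplot2::ggplot(object$labels,
                  ggplot2::aes(.data$lon, .data$lat,
                               fill = factor(.data$cluster))) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "cluster", x = "longitude", y = "latitude") +
    ggplot2::theme_minimal()
}

#' @describeIn gapscape-plots sorted per-species protection bars with the
#'   target lines, one panel per range-estimation approach.
#' @method autoplot gap_report
#' @export
autoplot.gap_report <- function(object, ...) {
  ggplot2::ggplot(gap_bars(object),
                  ggplot2::aes(.data$rank, .data$percent_protected,
                               fill = .data$endemic)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$targets, linetype = "dashed") +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = "species (sorted)", y = "% of range protected") +
    ggplot2::theme_minimal()
}

#' @describeIn gapscape-plots elevation histogram of a species profile.
#' @method autoplot species_profile
#' @export
autoplot.species_profile <- function(object, ...) {
  ggplot2::ggplot(object$elevation_hist,
                  ggplot2::aes(x = (.data$bin_lower + .data$bin_upper) / 2,
                               y = .data$count)) +
    ggplot2::geom_col(width = min(object$elevation_hist$bin_upper -
                                    object$elevation_hist$bin_lower),
                      fill = "steelblue") +
    ggplot2::labs(title = object$species_id, x = "elevation (m)",
                  y = "records") +
    ggplot2::theme_minimal()
}

#' Richness map on the analysis grid
#'
#' @param grid a [build_grid()] grid.
#' @param richness_tbl output of [richness()] on that grid.
#' @return a ggplot object.
#' @export
plot_richness <- function(grid, richness_tbl) {
  cells <- dplyr::inner_join(grid$cells, richness_tbl,
                             by = c(cell_id = "unit"))
  ggplot2::ggplot(cells) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$west, xmax = .data$east,
                                    ymin = .data$south, ymax = .data$north,
                                    fill = .data$richness)) +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "longitude", y = "latitude", fill = "species") +
    ggplot2::theme_minimal()
}

#' Climate envelope scatter for a species profile
#'
#' Background pixel cloud in BIO1 x BIO12 space with the species'
#' records overlaid.
#'
#' @param profile a [species_profile()].
#' @return a ggplot object.
#' @export
plot_climate_envelope <- function(profile) {
  ggplot2::ggplot(profile$climate$background,
                  ggplot2::aes(.data$BIO1, .data$BIO12)) +
    ggplot2::geom_point(size = 0.3, colour = "grey70") +
    ggplot2::geom_point(data = profile$climate$points, colour = "red",
                        size = 0.8) +
    ggplot2::labs(title = profile$species_id,
                  x = "annual mean temperature (°C)",
                  y = "annual precipitation (mm)") +
    ggplot2::theme_minimal()
}
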