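# ggplot2 figures for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot cumulative abundance curves
#'
#' One curve per land use: cumulative mean sqrt-abundance against rank.
#' Homogenization shows as curves that share a head and split in the tail.
#'
#' @param object A `rank_curve` from [cumulative_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rank_curve
#' @export
autoplot.rank_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$rank, .data$cumulative,
                                       colour = .data$land_use)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "OTU rank (decreasing abundance)",
                  y = "Cumulative mean √abundance",
                  colour = "Land use") +
    ggplot2::theme_minimal()
}

#' Plot a PCoA ordination
#'
#' @param object A `pcoa_ord` from [pcoa_ordination()].
#' @param metadata Optional site metadata; points are coloured by `colour`.
#' @param colour Metadata column to colour by (default `"country"`).
#' @param ... Unused.
#' @return A ggplot of the first two axes with variance-explained labels.
#' @method autoplot pcoa_ord
#' @export
autoplot.pcoa_ord <- function(object, metadata = NULL, colour = "country", ...) {
  d <- object$coordinates
  if (!is.null(metadata)) {
    d <- dplyr::left_join(d, metadata, by = "site_id")
  }
  pe <- round(100 * object$prop_explained[1:2], 1)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$Axis1, .data$Axis2)) +
    ggplot2::labs(x = paste0("PCoA 1 (", pe[1], "%)"),
                  y = paste0("PCoA 2 (", pe[2], "%)")) +
    ggplot2::theme_minimal()
  if (!is.null(metadata) && colour %in% names(d)) {
    shape_ok <- "land_use" %in% names(d)
    p + ggplot2::geom_point(ggplot2::aes(
      colour = .data[[colour]],
      shape = if (shape_ok) .data$land_use else NULL))
  } else {
    p + ggplot2::geom_point()
  }
}

#' Plot the occupancy-abundance relationship
#'
#' @param table A validated OTU table.
#' @return A ggplot: transformed abundance `log10(sqrt(reads))` against the
#'   number of occupied sites, with the Spearman rho in the subtitle.
#' @export
plot_occupancy_abundance <- function(table) {
  oa <- occupancy_abundance(table)
  sp <- attr(oa, "spearman")
  ggplot2::ggplot(oa, ggplot2::aes(.data$occupancy, .data$transformed_abundance)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::labs(x = "Occupancy (sites present)",
                  y = "log10(√total reads)",
                  subtitle = sprintf("Spearman rho = %.2f", sp[["rho"]])) +
    ggplot2::theme_minimal()
}

#' Plot diversity against the management-intensity index
#'
#' @param data Data frame with `intensity` and the response column.
#' @param response Unquoted response column (e.g. `richness`).
#' @return A ggplot with a linear trend and its 95% confidence band.
#' @export
plot_intensity <- function(data, response) {
  ggplot2::ggplot(data, ggplot2::aes(.data$intensity, {{ response }})) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "firebrick") +
    ggplot2::labs(x = "Agricultural intensity index (0-1)") +
    ggplot2::theme_minimal()
}
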