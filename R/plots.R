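#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_point
#'   geom_abline scale_fill_viridis_c scale_fill_gradient2 labs theme_minimal
#'   facet_wrap stat_summary
#' @export
ggplot2::autoplot

#' Plot the scene-mean greenspace seasonality of a cube
#'
#' @param object A `greenspace_cube`.
#' @param ... Unused.
#' @return A ggplot: mean coverage (with interquartile ribbon) per 10-day
#'   slot.
#' @export
autoplot.greenspace_cube <- function(object, ...) {
  df <- tidy.greenspace_cube(object)
  df <- dplyr::filter(df, is.finite(.data$coverage))
  ggplot(df, aes(x = .data$doy_mid, y = .data$coverage)) +
    stat_summary(fun = mean, geom = "line", linewidth = 0.8, colour = "#2e7d32") +
    stat_summary(fun.min = ~ stats::quantile(.x, 0.25),
                 fun.max = ~ stats::quantile(.x, 0.75),
                 geom = "ribbon", alpha = 0.25, fill = "#2e7d32") +
    labs(x = "Day of year (interval midpoint)", y = "Greenspace coverage",
         title = "Annual greenspace seasonality") +
    theme_minimal()
}

#' Map a cooling-efficiency raster
#'
#' @param object A `ce_map`.
#' @param ... Unused.
#' @return A ggplot raster map of CE in degC per 1% greenspace.
#' @export
autoplot.ce_map <- function(object, ...) {
  df <- tidy.ce_map(object)
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$ce)) +
    geom_raster() +
    scale_fill_viridis_c(option = "inferno", name = "CE (°C/%)") +
    labs(x = NULL, y = NULL,
         title = sprintf("Cooling efficiency (%dx%d window)",
                         object$window, object$window)) +
    theme_minimal()
}

#' Map the vegetation fraction of a fraction map
#'
#' @param object A `fraction_map`.
#' @param ... Unused.
#' @return A ggplot raster map of the vegetation fraction (G_max).
#' @export
autoplot.fraction_map <- function(object, ...) {
  df <- tidy.fraction_map(object)
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$vegetation)) +
    geom_raster() +
    scale_fill_viridis_c(limits = c(0, 1), name = "G_max") +
    labs(x = NULL, y = NULL, title = "Annual maximum greenspace fraction") +
    theme_minimal()
}

#' Scatter plot of block-level agreement
#'
#' @param a,b Block-mean tibbles from [block_aggregate()] (joined on block
#'   keys).
#' @return A ggplot scatter with the 1:1 line and r2/RMSE annotation.
#' @export
plot_block_agreement <- function(a, b) {
  j <- dplyr::inner_join(a, b, by = c("block_row", "block_col"),
                         suffix = c("_a", "_b"))
  m <- agreement_metrics(a, b)
  ggplot(j, aes(x = .data$mean_a, y = .data$mean_b)) +
    geom_point(alpha = 0.5, colour = "#2e7d32") +
    geom_abline(slope = 1, intercept = 0, linetype = 2) +
    labs(x = "Reference block mean", y = "Estimated block mean",
         title = sprintf("Block-level agreement (r2 = %.2f, RMSE = %.3f, n = %d)",
                         m$r2, m$rmse, m$n)) +
    theme_minimal()
}

#' Plot a phenology curve family
#'
#' @param params A [phenology_params()] object (or list of them).
#' @param doys Days of year to evaluate (default 1:365).
#' @return A ggplot of NDVI against day of year.
#' @export
plot_phenology_curve <- function(params, doys = 1:365) {
  if (inherits(params, "phenology_params")) params <- list(params)
  df <- purrr::imap_dfr(params, function(p, i) {
    tibble::tibble(curve = as.character(i), doy = doys,
                   ndvi = vegetation_ndvi_curve(p, doys))
  })
  ggplot(df, aes(x = .data$doy, y = .data$ndvi, colour = .data$curve)) +
    geom_line(linewidth = 0.8) +
    labs(x = "Day of year", y = "NDVI", colour = NULL,
         title = "Vegetation NDVI phenology") +
    theme_minimal()
}
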