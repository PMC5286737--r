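#' Base-graphics display of a map
#'
#' Quick-look `image()` display with the imaging orientation (row 1 at the
#' top).
#'
#' @param map matrix to display.
#' @param main title.
#' @param col palette.
#' @param ... passed to [graphics::image()].
#' @export
plot_map <- function(map, main = "", col = grDevices::hcl.colors(64, "Inferno"),
                     ...) {
  graphics::image(t(map[nrow(map):1, , drop = FALSE]), main = main, col = col,
                  axes = FALSE, asp = nrow(map) / ncol(map), ...)
}

#' Temperature map as a ggplot raster
#'
#' @param map matrix of temperature change (degC), or a `ctm_result` (its
#'   final frame is shown).
#' @param title plot title.
#' @return A ggplot object.
#' @export
plot_temperature <- function(map, title = "Temperature change (degC)") {
  if (inherits(map, "ctm_result")) {
    map <- map$temperature$dT[, , dim(map$temperature$dT)[3]]
  }
  df <- expand.grid(row = seq_len(nrow(map)), col = seq_len(ncol(map)))
  df$value <- as.vector(map)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "degC") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Normalized thermal-dose map as a ggplot raster
#'
#' @param object a `thermal_dose_map`.
#' @param ... unused.
#' @return A ggplot object; the fill is dose in lethal-threshold units
#'   (1 = 240 equivalent minutes at 43 degC), shown on a log10 scale.
#' @method autoplot thermal_dose_map
#' @export
autoplot.thermal_dose_map <- function(object, ...) {
  norm <- dose_normalized(object)
  df <- expand.grid(row = seq_len(nrow(norm)), col = seq_len(ncol(norm)))
  df$value <- log10(pmax(as.vector(norm), 1e-12))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "log10 dose\n(1 = lethal)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "Normalized thermal dose", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Concordance and Bland-Altman plots for lesion agreement
#'
#' @param object an `agreement_stats` object.
#' @param type `"bland_altman"` (differences vs means with bias and 95%
#'   limits of agreement) or `"scatter"` (paired dimensions with the fitted
#'   regression line and identity).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot agreement_stats
#' @export
autoplot.agreement_stats <- function(object,
                                     type = c("bland_altman", "scatter"),
                                     ...) {
  type <- match.arg(type)
  p <- object$pairs
  if (type == "scatter") {
    ggplot2::ggplot(p, ggplot2::aes(x = .data$t1w_mm, y = .data$td_mm)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
      ggplot2::geom_abline(slope = object$slope,
                           intercept = object$intercept, colour = "steelblue") +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::labs(x = "T1-w lesion dimension (mm)",
                    y = "Thermal-dose lesion dimension (mm)",
                    title = sprintf("r = %.2f, slope = %.2f, offset = %.2f mm",
                                    object$r, object$slope, object$intercept)) +
      ggplot2::theme_minimal()
  } else {
    df <- data.frame(mean = (p$td_mm + p$t1w_mm) / 2,
                     diff = p$td_mm - p$t1w_mm)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
      ggplot2::geom_hline(yintercept = object$bias, colour = "steelblue") +
      ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                          linetype = "dashed") +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::labs(x = "Mean of paired dimensions (mm)",
                    y = "Difference, TD - T1-w (mm)",
                    title = sprintf("Bias %.2f mm, 95%% LoA [%.2f, %.2f] mm",
                                    object$bias, object$loa_lower,
                                    object$loa_upper)) +
      ggplot2::theme_minimal()
  }
}

#' @importFrom ggplot2 .data
NULL

#' @importFrom graphics contour image
NULL
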