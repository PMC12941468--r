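# ggplot2 visualisations for the main result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a panel carbon report
#'
#' Per-individual carbonate carbon against attachment area, on log-log
#' axes, coloured by species. The straight lines are the species power laws
#' themselves, so departures flag records whose parameters were overridden.
#'
#' @param object a `panel_carbon_report`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot panel_carbon_report
#' @export
autoplot.panel_carbon_report <- function(object, ...) {
  ggplot2::ggplot(object$records,
                  ggplot2::aes(x = .data$area_cm2, y = .data$carbon_g,
                               colour = .data$species)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "attachment area (cm²)",
                  y = "carbonate carbon (g)",
                  title = sprintf("Panel carbon: %.4f g over %d individuals",
                                  object$totals$carbon_g, object$totals$n)) +
    ggplot2::theme_minimal()
}

#' Plot an allometric fit
#'
#' Calibration samples with the fitted power law overlaid, log-log.
#'
#' @param object an `allometric_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot allometric_fit
#' @export
autoplot.allometric_fit <- function(object, ...) {
  p <- object$params
  grid <- tibble::tibble(
    area_cm2 = exp(seq(log(min(object$data$area_cm2)),
                       log(max(object$data$area_cm2)), length.out = 100)))
  grid$W_g <- predict_dry_weight(grid$area_cm2, p)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$area_cm2, y = .data$W_g)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "attachment area (cm²)", y = "shell dry weight (g)",
      title = sprintf("%s: W = %d × %.4g · A^%.4g (R² = %.3f)",
                      p$species, p$valve_factor, p$alpha, p$beta,
                      object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot a synthetic or segmented scene
#'
#' Panel raster with instance bounding boxes overlaid.
#'
#' @param panel a `panel_image`.
#' @param instances optional instance table to overlay.
#' @return a ggplot.
#' @export
plot_scene <- function(panel, instances = NULL) {
  px <- panel$pixels
  df <- tidyr::expand_grid(y = seq_len(nrow(px)), x = seq_len(ncol(px)))
  df$value <- as.vector(t(px))
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(instances) && nrow(instances)) {
    g <- g + ggplot2::geom_rect(
      data = instances,
      ggplot2::aes(xmin = .data$x, xmax = .data$x + .data$w,
                   ymin = .data$y, ymax = .data$y + .data$h,
                   colour = .data$class),
      inherit.aes = FALSE, fill = NA, linewidth = 0.3)
  }
  g
}
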