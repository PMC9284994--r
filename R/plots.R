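#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bland-Altman plot
#'
#' Pairwise differences against pairwise means, with the mean difference
#' (solid) and the limits of agreement (dashed).
#'
#' @param object a `thermo_agreement` from [bland_altman()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.thermo_agreement <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_hline(yintercept = object$mean_diff, linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Mean of methods", y = "Difference (a - b)",
                  title = sprintf("Bland-Altman (n = %d): %.3g [%.3g, %.3g]",
                                  object$n, object$mean_diff,
                                  object$loa_low, object$loa_high)) +
    ggplot2::theme_minimal()
}

#' ROI temperature curve plot
#'
#' ROI-mean temperature change versus time, with the return-to-baseline
#' tolerance marked.
#'
#' @param object a `roi_curve` from [roi_mean_curve()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.roi_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$time_s,
                                             y = .data$mean_dT_C)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = object$epsilon_C, linetype = "dotted") +
    ggplot2::labs(x = "Time (s)", y = "ROI mean ΔT (°C)",
                  title = sprintf("Peak %.1f °C at %.0f s", object$max_dT_C,
                                  object$time_at_max_s)) +
    ggplot2::theme_minimal()
}

#' Dose-map slice plot
#'
#' CEM43 map of one slice as a raster with isodose contours overlaid.
#'
#' @param dose a [dose_map()].
#' @param slice slice index.
#' @param levels contour levels, equivalent minutes.
#' @return a ggplot.
#' @export
plot_dose_slice <- function(dose, slice = 1L, levels = c(10, 70, 240)) {
  abort_if(!inherits(dose, "dose_map"), "dose must be a dose_map")
  d <- dim(dose$cem43)
  abort_if(slice < 1 || slice > d[3], "slice out of range")
  sp <- dose$geometry$pixel_spacing_mm
  df <- expand.grid(x_mm = (seq_len(d[1]) - 1) * sp[1],
                    y_mm = (seq_len(d[2]) - 1) * sp[2])
  df$cem43 <- as.vector(dose$cem43[, , slice])
  cont <- isodose_contours(dose, levels)
  cont <- cont[cont$slice == slice, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x_mm, y = .data$y_mm)) +
    ggplot2::geom_raster(ggplot2::aes(fill = log10(.data$cem43 + 1))) +
    ggplot2::scale_fill_viridis_c(name = "log10(CEM43 + 1)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
  if (nrow(cont) > 0) {
    p <- p + ggplot2::geom_path(
      data = cont,
      ggplot2::aes(group = interaction(.data$level, .data$contour_id)),
      colour = "white")
  }
  p
}
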