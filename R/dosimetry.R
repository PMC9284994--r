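#' Thermal dose parameters
#'
#' Parameters of the Sapareto-Dewey cumulative-equivalent-minutes model:
#' CEM43 accumulates as `R^(43 - T)` equivalent minutes per real minute, with
#' `R = 0.25` below the 43 degC reference and `R = 0.50` at or above it. The
#' necrotic-zone boundary is drawn at CEM43 strictly greater than
#' `threshold_CEM` (default 70, an empirical soft-tissue necrosis level).
#'
#' @param R_below,R_at_or_above dose rate constants in (0, 1).
#' @param reference_temp_C reference temperature, degC (43).
#' @param threshold_CEM positive necrosis threshold, equivalent minutes.
#' @param baseline_temp_C absolute tissue baseline added to measured
#'   temperature change (default 37 degC; a declared parameter, not measured).
#' @return a `dose_params` list.
#' @export
dose_params <- function(R_below = 0.25, R_at_or_above = 0.50,
                        reference_temp_C = 43, threshold_CEM = 70,
                        baseline_temp_C = 37) {
  for (r in c(R_below, R_at_or_above))
    abort_if(!is_scalar_num(r) || r <= 0 || r >= 1, "R values must lie in (0, 1)")
  abort_if(!is_scalar_num(threshold_CEM) || threshold_CEM <= 0,
           "threshold_CEM must be positive")
  structure(list(R_below = R_below, R_at_or_above = R_at_or_above,
                 reference_temp_C = reference_temp_C,
                 threshold_CEM = threshold_CEM,
                 baseline_temp_C = baseline_temp_C),
            class = "dose_params")
}

#' Accumulate CEM43 thermal dose from a temperature series
#'
#' Sapareto-Dewey accumulation: per pixel,
#' `CEM43 = sum_t R^(43 - T_t) * dt` with `dt` in minutes and `T_t` the
#' average of the two adjacent frames' absolute temperatures (trapezoid-style
#' "average temperature during dt"), and `R` switched at the 43 degC
#' reference on that average.
#'
#' @param temps a [temperature_series()].
#' @param params a [dose_params()]; its `baseline_temp_C` is overridden by the
#'   series' own baseline.
#' @return a [dose_map()] of cumulative equivalent minutes.
#' @examples
#' # constant 44 degC for 35 min: dose = 0.5^(-1) * 35 = 70 CEM43
#' @export
accumulate_cem43 <- function(temps, params = dose_params()) {
  abort_if(!inherits(temps, "temperature_series"), "temps must be a temperature_series")
  nf <- dim(temps$delta_T)[4]
  abort_if(nf < 2L, "need at least 2 frames to accumulate dose")
  base <- temps$baseline_temp_C
  abort_if(!is_scalar_num(base), "baseline_temp_C must be set")
  ref <- params$reference_temp_C
  cem <- array(0, dim = dim(temps$delta_T)[1:3])
  for (i in seq_len(nf - 1L)) {
    t_avg <- base + (arr_frame(temps$delta_T, i) + arr_frame(temps$delta_T, i + 1L)) / 2
    dt_min <- (temps$timestamps_s[i + 1L] - temps$timestamps_s[i]) / 60
    r <- ifelse(t_avg >= ref, params$R_at_or_above, params$R_below)
    cem <- cem + r^(ref - t_avg) * dt_min
  }
  dose_map(cem, temps$geometry)
}

#' Necrotic-zone volume by thresholded pixel counting
#'
#' Counts pixels with dose strictly above the CEM43 threshold and multiplies
#' by the three voxel dimensions. No interpolation and no connectivity
#' filtering: raw pixel-grid counting.
#'
#' @param dose a [dose_map()].
#' @param params a [dose_params()] (supplies the threshold).
#' @param threshold override threshold, equivalent minutes.
#' @return one-row tibble: `volume_cm3`, `pixel_count`, `threshold_used`,
#'   `voxel_volume_cm3`.
#' @export
dose_volume <- function(dose, params = dose_params(), threshold = params$threshold_CEM) {
  abort_if(!inherits(dose, "dose_map"), "dose must be a dose_map")
  abort_if(!is_scalar_num(threshold) || threshold <= 0, "threshold must be positive")
  vox <- voxel_volume_cm3(dose$geometry)
  count <- sum(dose$cem43 > threshold)   # strict: CEM43 > threshold
  tibble::tibble(volume_cm3 = count * vox, pixel_count = as.integer(count),
                 threshold_used = threshold, voxel_volume_cm3 = vox)
}

#' Isodose contours
#'
#' Marching-squares contour lines of the per-slice dose maps at the requested
#' CEM43 levels, in physical millimetre coordinates (pixel centres; the first
#' pixel centre sits at 0 mm).
#'
#' @param dose a [dose_map()].
#' @param levels positive contour levels, equivalent minutes.
#' @return tibble with `slice`, `level`, `contour_id`, `x_mm`, `y_mm`; zero
#'   rows when no contour exists at any level.
#' @export
isodose_contours <- function(dose, levels = c(10, 70, 240)) {
  abort_if(!inherits(dose, "dose_map"), "dose must be a dose_map")
  abort_if(any(levels <= 0), "levels must be positive")
  d <- dim(dose$cem43)
  sp <- dose$geometry$pixel_spacing_mm
  x <- (seq_len(d[1]) - 1) * sp[1]
  y <- (seq_len(d[2]) - 1) * sp[2]
  res <- list()
  for (s in seq_len(d[3])) {
    z <- dose$cem43[, , s]
    if (diff(range(z)) == 0) next          # flat slice: no contour at any level
    cl <- grDevices::contourLines(x, y, z, levels = levels)
    for (k in seq_along(cl)) {
      res[[length(res) + 1L]] <- tibble::tibble(
        slice = s, level = cl[[k]]$level, contour_id = k,
        x_mm = cl[[k]]$x, y_mm = cl[[k]]$y)
    }
  }
  if (length(res) == 0) {
    return(tibble::tibble(slice = integer(), level = numeric(),
                          contour_id = integer(), x_mm = numeric(),
                          y_mm = numeric()))
  }
  dplyr::bind_rows(res)
}
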