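#' Image geometry
#'
#' Physical geometry shared by all image-stack containers: in-plane pixel
#' spacing and through-plane slice thickness, both in millimetres.
#'
#' @param pixel_spacing_mm length-2 positive numeric, mm per pixel (row, col).
#' @param slice_thickness_mm positive scalar, mm.
#' @return a `thermo_geometry` list.
#' @export
image_geometry <- function(pixel_spacing_mm, slice_thickness_mm) {
  pixel_spacing_mm <- rep_len(as.numeric(pixel_spacing_mm), 2L)
  abort_if(any(!is.finite(pixel_spacing_mm)) || any(pixel_spacing_mm <= 0),
           "pixel_spacing_mm must be positive and finite")
  abort_if(!is_scalar_num(slice_thickness_mm) || slice_thickness_mm <= 0,
           "slice_thickness_mm must be a positive scalar")
  structure(list(pixel_spacing_mm = pixel_spacing_mm,
                 slice_thickness_mm = slice_thickness_mm),
            class = "thermo_geometry")
}

#' @export
print.thermo_geometry <- function(x, ...) {
  cat(sprintf("<geometry: %.4g x %.4g mm pixels, %.4g mm slices>\n",
              x$pixel_spacing_mm[1], x$pixel_spacing_mm[2], x$slice_thickness_mm))
  invisible(x)
}

voxel_volume_cm3 <- function(geometry) {
  prod(geometry$pixel_spacing_mm) * geometry$slice_thickness_mm / 1000
}

#' Wrapped-phase image time series
#'
#' Container for a multislice 2-D phase acquisition: a 4-D array of wrapped
#' phase (radians, in (-pi, pi]) indexed `[row, col, slice, frame]`, the frame
#' timestamps, the geometry, and the number of leading pre-heating baseline
#' frames.
#'
#' @param phase 4-D numeric array of wrapped phase, radians.
#' @param timestamps_s strictly increasing numeric vector, one per frame.
#' @param geometry a [image_geometry()].
#' @param baseline_frames integer >= 1, count of leading pre-heating frames.
#' @return a `phase_series` object.
#' @export
phase_series <- function(phase, timestamps_s, geometry, baseline_frames = 1L) {
  abort_if(length(dim(phase)) != 4L, "phase must be a 4-D array [row, col, slice, frame]")
  abort_if(length(timestamps_s) != dim(phase)[4],
           "timestamps_s must have one entry per frame")
  abort_if(any(diff(timestamps_s) <= 0), "timestamps_s must be strictly increasing")
  abort_if(any(phase > pi + 1e-9 | phase <= -pi - 1e-9, na.rm = TRUE),
           "phase values must lie in (-pi, pi]")
  baseline_frames <- as.integer(baseline_frames)
  abort_if(baseline_frames < 1L || baseline_frames >= dim(phase)[4],
           "baseline_frames must be >= 1 and leave at least one dynamic frame")
  structure(list(phase = phase, timestamps_s = as.numeric(timestamps_s),
                 geometry = geometry, baseline_frames = baseline_frames),
            class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  d <- dim(x$phase)
  cat(sprintf("<phase_series: %d x %d x %d slices x %d frames, %d baseline>\n",
              d[1], d[2], d[3], d[4], x$baseline_frames))
  invisible(x)
}

#' Temperature-change image time series
#'
#' Per-frame temperature change maps (degrees C relative to baseline) with the
#' declared absolute baseline temperature, so `T_t = baseline_temp_C + delta_T`.
#'
#' @param delta_T 4-D numeric array `[row, col, slice, frame]`, degrees C.
#' @param timestamps_s strictly increasing numeric vector, one per frame.
#' @param geometry a [image_geometry()].
#' @param baseline_temp_C absolute baseline temperature, degrees C (default 37).
#' @return a `temperature_series` object.
#' @export
temperature_series <- function(delta_T, timestamps_s, geometry, baseline_temp_C = 37) {
  abort_if(length(dim(delta_T)) != 4L, "delta_T must be a 4-D array [row, col, slice, frame]")
  abort_if(length(timestamps_s) != dim(delta_T)[4],
           "timestamps_s must have one entry per frame")
  abort_if(any(diff(timestamps_s) <= 0), "timestamps_s must be strictly increasing")
  abort_if(any(!is.finite(delta_T)), "delta_T must be finite everywhere")
  structure(list(delta_T = delta_T, timestamps_s = as.numeric(timestamps_s),
                 geometry = geometry, baseline_temp_C = baseline_temp_C),
            class = "temperature_series")
}

#' @export
print.temperature_series <- function(x, ...) {
  d <- dim(x$delta_T)
  cat(sprintf(
    "<temperature_series: %d x %d x %d slices x %d frames, baseline %.1f degC, peak dT %.2f degC>\n",
    d[1], d[2], d[3], d[4], x$baseline_temp_C, max(x$delta_T)))
  invisible(x)
}

#' Cumulative thermal dose map
#'
#' Per-pixel cumulative equivalent minutes at 43 degrees C (CEM43), one 2-D map
#' per slice, with geometry for volumetry.
#'
#' @param cem43 3-D nonnegative numeric array `[row, col, slice]`, minutes.
#' @param geometry a [image_geometry()].
#' @return a `dose_map` object.
#' @export
dose_map <- function(cem43, geometry) {
  abort_if(length(dim(cem43)) != 3L, "cem43 must be a 3-D array [row, col, slice]")
  abort_if(any(cem43 < 0, na.rm = TRUE), "cem43 must be nonnegative")
  structure(list(cem43 = cem43, geometry = geometry), class = "dose_map")
}

#' @export
print.dose_map <- function(x, ...) {
  d <- dim(x$cem43)
  cat(sprintf("<dose_map: %d x %d x %d slices, max CEM43 %.3g min>\n",
              d[1], d[2], d[3], max(x$cem43)))
  invisible(x)
}
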