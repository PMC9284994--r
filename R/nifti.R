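#' Minimal NIfTI-1 writer
#'
#' Writes a numeric array (2-D to 4-D) as a single-file little-endian NIfTI-1
#' image (`.nii` or gzipped `.nii.gz`), float64 voxels, with pixel spacings in
#' mm and the frame interval in seconds carried in `pixdim`. No installed R
#' package provides NIfTI support in this stack, so the format is implemented
#' directly; files are readable by standard tools (e.g. nibabel).
#'
#' @param arr numeric array, up to 4 dimensions.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param pixdim_mm spatial spacings, mm (recycled to 3).
#' @param dt_s temporal spacing for the 4th dimension, seconds.
#' @param description short free-text tag (<= 79 chars).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(arr, path, pixdim_mm = c(1, 1, 1), dt_s = 0,
                        description = "thermodose") {
  abort_if(!is.numeric(arr) || is.null(dim(arr)), "arr must be a numeric array")
  nd <- length(dim(arr))
  abort_if(nd < 2L || nd > 4L, "arr must have 2 to 4 dimensions")
  pixdim_mm <- rep_len(as.numeric(pixdim_mm), 3L)
  dims <- c(nd, dim(arr), rep(1L, 7L - nd))
  pd <- c(1, pixdim_mm, dt_s, 0, 0, 0)

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wc <- function(s, width) {
    raw_s <- charToRaw(s)
    writeBin(c(raw_s, raw(width - length(raw_s))), con)
  }
  wi(348, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                       # data_type..dim_info (unused)
  wi(dims, 2)                                  # dim[8]
  wf(c(0, 0, 0)); wi(0, 2)                     # intent_p1..3, intent_code
  wi(64, 2); wi(64, 2); wi(0, 2)               # datatype float64, bitpix, slice_start
  wf(pd)                                       # pixdim[8]
  wf(352)                                      # vox_offset
  wf(1); wf(0)                                 # scl_slope, scl_inter
  wi(0, 2); writeBin(as.raw(c(0, 10)), con)    # slice_end, slice_code, xyzt_units (mm | s)
  wf(c(0, 0, 0, 0))                            # cal_max, cal_min, slice_duration, toffset
  wi(c(0, 0), 4)                               # glmax, glmin
  wc(substr(description, 1, 79), 80)           # descrip
  writeBin(raw(24), con)                       # aux_file
  wi(c(0, 1), 2)                               # qform_code, sform_code
  wf(rep(0, 6))                                # quatern, qoffset
  wf(c(pixdim_mm[1], 0, 0, 0))                 # srow_x
  wf(c(0, pixdim_mm[2], 0, 0))                 # srow_y
  wf(c(0, 0, pixdim_mm[3], 0))                 # srow_z
  writeBin(raw(16), con)                       # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)   # magic
  writeBin(raw(4), con)                        # no extensions
  writeBin(as.numeric(arr), con, size = 8, endian = "little")
  invisible(path)
}

#' Minimal NIfTI-1 reader
#'
#' Reads single-file little-endian NIfTI-1 images with float32 or float64
#' voxels (the subset this package writes).
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return list with `data` (numeric array), `pixdim_mm` (length 3), `dt_s`.
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 352)
  ri <- function(off, size, n = 1L)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  rf <- function(off, n = 1L)
    readBin(hdr[(off + 1):(off + 4 * n)], "numeric", n = n, size = 4,
            endian = "little")
  abort_if(ri(0, 4) != 348L, "not a NIfTI-1 file (bad sizeof_hdr)")
  magic <- rawToChar(hdr[345:347])
  abort_if(!magic %in% c("n+1", "ni1"), "not a NIfTI-1 file (bad magic)")
  dims <- ri(40, 2, 8)
  nd <- dims[1]
  abort_if(nd < 1L || nd > 4L, "only 1-4 dimensional images supported")
  shape <- dims[2:(1 + nd)]
  datatype <- ri(70, 2)
  size <- switch(as.character(datatype), "16" = 4L, "64" = 8L,
                 stop("unsupported NIfTI datatype: ", datatype, call. = FALSE))
  pd <- rf(76, 8)
  vox_offset <- rf(108)
  skip <- vox_offset - 352
  if (skip > 0) readBin(con, "raw", n = skip)
  n_vox <- prod(shape)
  data <- readBin(con, "numeric", n = n_vox, size = size, endian = "little")
  slope <- rf(112); inter <- rf(116)
  if (is.finite(slope) && slope != 0 && !(slope == 1 && inter == 0))
    data <- data * slope + inter
  dim(data) <- shape
  list(data = data, pixdim_mm = pd[2:4], dt_s = pd[5])
}

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Write / read a phase series as NIfTI + JSON sidecar
#'
#' The 4-D wrapped-phase array goes to `path` (`.nii` / `.nii.gz`); frame
#' timestamps, baseline-frame count and geometry go to a JSON sidecar next to
#' it.
#'
#' @param series a [phase_series()].
#' @param path output NIfTI path.
#' @return `path` ([write_phase_series()]) or a [phase_series()]
#'   ([read_phase_series()]).
#' @export
write_phase_series <- function(series, path) {
  geo <- series$geometry
  write_nifti(series$phase, path,
              pixdim_mm = c(geo$pixel_spacing_mm, geo$slice_thickness_mm),
              dt_s = if (length(series$timestamps_s) > 1)
                diff(series$timestamps_s)[1] else 0,
              description = "thermodose wrapped phase")
  jsonlite::write_json(list(timestamps_s = series$timestamps_s,
                            baseline_frames = series$baseline_frames,
                            pixel_spacing_mm = geo$pixel_spacing_mm,
                            slice_thickness_mm = geo$slice_thickness_mm),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phase_series
#' @export
read_phase_series <- function(path) {
  img <- read_nifti(path)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  phase_series(img$data, meta$timestamps_s,
               image_geometry(meta$pixel_spacing_mm, meta$slice_thickness_mm),
               baseline_frames = meta$baseline_frames)
}

#' Write / read a temperature series as NIfTI + JSON sidecar
#'
#' @param temps a [temperature_series()].
#' @param path output NIfTI path.
#' @return `path` or a [temperature_series()].
#' @export
write_temperature_series <- function(temps, path) {
  geo <- temps$geometry
  write_nifti(temps$delta_T, path,
              pixdim_mm = c(geo$pixel_spacing_mm, geo$slice_thickness_mm),
              dt_s = if (length(temps$timestamps_s) > 1)
                diff(temps$timestamps_s)[1] else 0,
              description = "thermodose delta-T degC")
  jsonlite::write_json(list(timestamps_s = temps$timestamps_s,
                            baseline_temp_C = temps$baseline_temp_C,
                            pixel_spacing_mm = geo$pixel_spacing_mm,
                            slice_thickness_mm = geo$slice_thickness_mm),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_temperature_series
#' @export
read_temperature_series <- function(path) {
  img <- read_nifti(path)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  temperature_series(img$data, meta$timestamps_s,
                     image_geometry(meta$pixel_spacing_mm, meta$slice_thickness_mm),
                     baseline_temp_C = meta$baseline_temp_C)
}

#' Write / read a dose map as NIfTI
#'
#' @param dose a [dose_map()].
#' @param path output NIfTI path.
#' @return `path` or a [dose_map()].
#' @export
write_dose_map <- function(dose, path) {
  geo <- dose$geometry
  write_nifti(dose$cem43, path,
              pixdim_mm = c(geo$pixel_spacing_mm, geo$slice_thickness_mm),
              description = "thermodose CEM43 minutes")
  invisible(path)
}

#' @rdname write_dose_map
#' @export
read_dose_map <- function(path) {
  img <- read_nifti(path)
  dose_map(img$data, image_geometry(img$pixdim_mm[1:2], img$pixdim_mm[3]))
}

#' Write an ROI temperature curve as CSV
#'
#' Columns `time_s`, `mean_dT_C`.
#'
#' @param curve a `roi_curve` from [roi_mean_curve()].
#' @param path CSV path.
#' @export
write_roi_curve_csv <- function(curve, path) {
  readr::write_csv(curve$curve, path)
  invisible(path)
}
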