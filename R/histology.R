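#' Build a traced-section table
#'
#' Assembles per-slice lesion tracings (as produced by planimetry on stained
#' brain sections) into the tidy table the volumetry functions consume.
#'
#' @param slice_index unique integer section indices (anterior to posterior).
#' @param area_cm2 nonnegative traced lesion area per section, cm^2.
#' @param full_thickness logical; did the lesion go through the posterior face
#'   of the section? Recycled. Default `TRUE`.
#' @param slice_thickness_cm positive section thickness, cm (default 0.5,
#'   i.e. 5 mm slabs).
#' @param scale_px_per_cm optional calibration provenance of the traced areas.
#' @return tibble of class `histology_sections` with one row per section and
#'   attributes `slice_thickness_cm`, `scale_px_per_cm`.
#' @export
histology_sections <- function(slice_index, area_cm2, full_thickness = TRUE,
                               slice_thickness_cm = 0.5,
                               scale_px_per_cm = NA_real_) {
  slice_index <- as.integer(slice_index)
  abort_if(anyDuplicated(slice_index) > 0, "slice indices must be unique")
  abort_if(any(!is.finite(area_cm2)) || any(area_cm2 < 0),
           "areas must be finite and nonnegative")
  abort_if(!is_scalar_num(slice_thickness_cm) || slice_thickness_cm <= 0,
           "slice_thickness_cm must be a positive scalar")
  out <- tibble::tibble(slice_index = slice_index,
                        area_cm2 = as.numeric(area_cm2),
                        full_thickness = rep_len(as.logical(full_thickness),
                                                 length(slice_index)))
  attr(out, "slice_thickness_cm") <- slice_thickness_cm
  attr(out, "scale_px_per_cm") <- scale_px_per_cm
  class(out) <- c("histology_sections", class(out))
  out
}

#' Calibrate an image scale from a ruler
#'
#' Planimetry calibration: a line of known physical length is drawn on the
#' imaged ruler, giving pixels per centimetre. Traced pixel areas are then
#' converted with [px_area_to_cm2()].
#'
#' @param ruler_px measured line length in pixels (> 0).
#' @param ruler_cm physical line length in cm (> 0, default 1).
#' @return pixels per cm (scalar).
#' @examples
#' calibrate_scale(150)            # 150 px/cm
#' px_area_to_cm2(4500, calibrate_scale(150))  # 0.2 cm^2
#' @export
calibrate_scale <- function(ruler_px, ruler_cm = 1) {
  abort_if(!is_scalar_num(ruler_px) || ruler_px <= 0, "ruler_px must be positive")
  abort_if(!is_scalar_num(ruler_cm) || ruler_cm <= 0, "ruler_cm must be positive")
  ruler_px / ruler_cm
}

#' Convert a traced pixel area to cm^2
#'
#' @param pixel_area area in pixels^2.
#' @param scale_px_per_cm calibration from [calibrate_scale()].
#' @return area in cm^2: `pixel_area / scale_px_per_cm^2`.
#' @export
px_area_to_cm2 <- function(pixel_area, scale_px_per_cm) {
  abort_if(!is.numeric(pixel_area) || any(pixel_area < 0),
           "pixel_area must be nonnegative")
  abort_if(!is_scalar_num(scale_px_per_cm) || scale_px_per_cm <= 0,
           "scale_px_per_cm must be positive")
  pixel_area / scale_px_per_cm^2
}

#' Lesion volume from traced sections
#'
#' Reproduces slab volumetry on stained sections: each traced area is
#' multiplied by the section thickness if the ablation went through the
#' posterior face of the slab, and the per-section volumes are summed.
#' Sections where the lesion does not reach the posterior face contribute
#' `area * partial_fraction * thickness` (default 0).
#'
#' @param sections a [histology_sections()] table (or any data frame with
#'   `area_cm2` and `full_thickness` columns).
#' @param slice_thickness_cm section thickness in cm; defaults to the table's
#'   `slice_thickness_cm` attribute, else 0.5.
#' @param partial_fraction thickness fraction credited to not-through sections,
#'   in `[0, 1]` (default 0).
#' @return total lesion volume, cm^3.
#' @examples
#' s <- histology_sections(1:3, c(0.4, 0.6, 0.2))
#' histology_volume(s)  # 0.6 cm^3
#' @export
histology_volume <- function(sections, slice_thickness_cm = NULL,
                             partial_fraction = 0) {
  abort_if(!is.data.frame(sections) || nrow(sections) == 0,
           "sections must be a nonempty data frame")
  abort_if(!all(c("area_cm2", "full_thickness") %in% names(sections)),
           "sections must have area_cm2 and full_thickness columns")
  if (is.null(slice_thickness_cm)) {
    slice_thickness_cm <- attr(sections, "slice_thickness_cm")
    if (is.null(slice_thickness_cm)) slice_thickness_cm <- 0.5
  }
  abort_if(!is_scalar_num(partial_fraction) || partial_fraction < 0 ||
             partial_fraction > 1, "partial_fraction must be in [0, 1]")
  frac <- ifelse(sections$full_thickness, 1, partial_fraction)
  sum(sections$area_cm2 * frac * slice_thickness_cm)
}

#' Compare two observers' volume measurements
#'
#' Paired comparison of repeated volumetry by two raters: per-pair differences,
#' their mean and SEM, and a two-sided paired t-test.
#'
#' @param volumes_p1,volumes_p2 equal-length numeric vectors, n >= 2.
#' @return list of class `observer_comparison` with `differences` and a
#'   one-row `summary` tibble (`n`, `mean_diff`, `sd_diff`, `sem_diff`,
#'   `t_stat`, `p_value`).
#' @export
observer_compare <- function(volumes_p1, volumes_p2) {
  check_paired(volumes_p1, volumes_p2, min_n = 2L)
  tt <- paired_t(volumes_p1, volumes_p2)
  structure(list(
    differences = volumes_p1 - volumes_p2,
    summary = tibble::tibble(n = tt$n, mean_diff = tt$mean_diff,
                             sd_diff = tt$sd_diff,
                             sem_diff = tt$sd_diff / sqrt(tt$n),
                             t_stat = tt$t_stat, p_value = tt$p_value)
  ), class = "observer_comparison")
}

#' @export
print.observer_comparison <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Observer comparison (n = %d): mean diff %.4g +/- %.4g (SEM), p = %.4g\n",
              s$n, s$mean_diff, s$sem_diff, s$p_value))
  invisible(x)
}

#' Read / write traced-section tables as CSV
#'
#' Columns: `slice_index`, `area_cm2`, `full_thickness`; section thickness is
#' carried in a `slice_thickness_cm` column (constant) so the file round-trips.
#'
#' @param path CSV file path.
#' @return [read_sections_csv()] returns a [histology_sections()] table.
#' @export
read_sections_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  abort_if(!all(c("slice_index", "area_cm2") %in% names(df)),
           "CSV must have slice_index and area_cm2 columns")
  ft <- if ("full_thickness" %in% names(df)) as.logical(df$full_thickness) else TRUE
  thk <- if ("slice_thickness_cm" %in% names(df)) df$slice_thickness_cm[1] else 0.5
  histology_sections(df$slice_index, df$area_cm2, ft, slice_thickness_cm = thk)
}

#' @rdname read_sections_csv
#' @param sections a [histology_sections()] table.
#' @export
write_sections_csv <- function(sections, path) {
  thk <- attr(sections, "slice_thickness_cm")
  if (is.null(thk)) thk <- 0.5
  out <- tibble::tibble(slice_index = sections$slice_index,
                        area_cm2 = sections$area_cm2,
                        full_thickness = sections$full_thickness,
                        slice_thickness_cm = thk)
  readr::write_csv(out, path)
  invisible(path)
}
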