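#' MR acquisition parameters for PRFS thermometry
#'
#' Holds the constants of the proton-resonance-frequency-shift relation
#' `delta_phi = gamma * alpha * B0 * TE * delta_T`: field strength, echo time,
#' the PRFS thermal coefficient (nominal -0.01 ppm/degC for water-based
#' tissue; heating therefore produces a *negative* corrected phase shift) and
#' the proton gyromagnetic ratio.
#'
#' @param B0 static field strength, tesla (> 0).
#' @param TE echo time, seconds (> 0). Default 13.2 ms.
#' @param alpha_ppm_per_C PRFS thermal coefficient, ppm/degC (nonzero;
#'   default -0.01).
#' @param gamma_rad_s_T gyromagnetic ratio, rad/s/T (default 2*pi*42.576e6).
#' @return an `acq_params` list.
#' @export
acq_params <- function(B0 = 3, TE = 13.2e-3, alpha_ppm_per_C = -0.01,
                       gamma_rad_s_T = 2 * pi * 42.576e6) {
  abort_if(!is_scalar_num(B0) || B0 <= 0, "B0 must be positive")
  abort_if(!is_scalar_num(TE) || TE <= 0, "TE must be positive")
  abort_if(!is_scalar_num(alpha_ppm_per_C) || alpha_ppm_per_C == 0,
           "alpha must be nonzero")
  abort_if(!is_scalar_num(gamma_rad_s_T) || gamma_rad_s_T <= 0,
           "gamma must be positive")
  structure(list(B0 = B0, TE = TE, alpha_ppm_per_C = alpha_ppm_per_C,
                 gamma_rad_s_T = gamma_rad_s_T), class = "acq_params")
}

# rad per degC: gamma * alpha * B0 * TE (alpha converted from ppm)
phase_per_degC <- function(acq) {
  acq$gamma_rad_s_T * acq$alpha_ppm_per_C * 1e-6 * acq$B0 * acq$TE
}

#' Wrapped phase difference against the baseline
#'
#' Subtracts the baseline phase from one dynamic frame, correctly wrapped via
#' the complex-ratio angle. The baseline is the circular mean of all declared
#' pre-heating frames.
#'
#' @param series a [phase_series()].
#' @param frame frame index (1-based), must be past the baseline block.
#' @return 3-D array `[row, col, slice]` of wrapped phase differences.
#' @export
phase_difference <- function(series, frame) {
  abort_if(!inherits(series, "phase_series"), "series must be a phase_series")
  nf <- dim(series$phase)[4]
  abort_if(!is_scalar_num(frame) || frame < series$baseline_frames + 1 || frame > nf,
           sprintf("frame must be in [%d, %d]", series$baseline_frames + 1L, nf))
  base <- baseline_phase(series)
  wrap_phase(arr_frame(series$phase, frame) - base)
}

# circular mean over the baseline frames, per pixel
baseline_phase <- function(series) {
  nb <- series$baseline_frames
  d <- dim(series$phase)[1:3]
  z <- array(0 + 0i, dim = d)
  for (f in seq_len(nb)) z <- z + exp(1i * arr_frame(series$phase, f))
  out <- Arg(z)
  dim(out) <- d
  out
}

#' Edge-contour reference region
#'
#' Builds the non-heated correction region: a ring of `width_px` morphological
#' shells around the outer edge of the brain mask (mask minus the mask eroded
#' `width_px` times with a 3x3 structuring element), computed per slice. This
#' ring is where the drift polynomial is fitted.
#'
#' @param brain_mask logical matrix (one slice) or 3-D logical array
#'   `[row, col, slice]`.
#' @param width_px ring width in pixels (default 3).
#' @return logical object of the same shape marking the reference ring.
#' @export
make_edge_reference <- function(brain_mask, width_px = 3L) {
  width_px <- as.integer(width_px)
  abort_if(width_px < 1L, "width_px must be >= 1 (empty region otherwise)")
  if (is.matrix(brain_mask)) return(edge_ring_slice(brain_mask, width_px))
  abort_if(length(dim(brain_mask)) != 3L, "brain_mask must be a matrix or 3-D array")
  out <- brain_mask
  for (s in seq_len(dim(brain_mask)[3]))
    out[, , s] <- edge_ring_slice(brain_mask[, , s], width_px)
  out
}

edge_ring_slice <- function(mask, width_px) {
  mask <- mask & !is.na(mask)
  abort_if(!any(mask), "brain mask is empty on a slice")
  eroded <- mask
  for (k in seq_len(width_px)) {
    eroded <- erode3x3(eroded)
    abort_if(!any(eroded),
             sprintf("mask eroded to empty after %d of %d shells", k, width_px))
  }
  mask & !eroded
}

# binary erosion with a 3x3 box (8-connectivity shell), outside counts as FALSE
erode3x3 <- function(mask) {
  out <- mask
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    shifted <- matrix(FALSE, nrow(mask), ncol(mask))
    ri <- seq_len(nrow(mask)) + di
    rj <- seq_len(ncol(mask)) + dj
    ok_i <- ri >= 1 & ri <= nrow(mask)
    ok_j <- rj >= 1 & rj <= ncol(mask)
    shifted[ok_i, ok_j] <- mask[ri[ok_i], rj[ok_j]]
    out <- out & shifted
  }
  out
}

# monomial design matrix, total degree <= order, on normalised [-1, 1] coords
poly_design <- function(i, j, n, m, order) {
  x <- 2 * (i - 1) / max(n - 1, 1) - 1
  y <- 2 * (j - 1) / max(m - 1, 1) - 1
  cols <- list()
  for (p in 0:order) for (q in 0:(order - p))
    cols[[length(cols) + 1L]] <- x^p * y^q
  do.call(cbind, cols)
}

#' Fit a background drift polynomial on the reference region
#'
#' Least-squares fit of a 2-D spatial polynomial (total degree `order`,
#' normalised per-slice pixel coordinates) to a phase-difference map restricted
#' to the non-heated reference region, returning the surface evaluated over the
#' whole field of view. With `order = 2` this is the B0-drift correction
#' surface subtracted by the referenced PRFS method.
#'
#' @param phase_diff matrix (one slice) or 3-D array `[row, col, slice]`.
#' @param region logical object of the same shape (see
#'   [make_edge_reference()]).
#' @param order total polynomial degree (default 2).
#' @return fitted surface with the same shape as `phase_diff`.
#' @export
fit_drift_polynomial <- function(phase_diff, region, order = 2L) {
  order <- as.integer(order)
  abort_if(order < 0L, "order must be >= 0")
  if (is.matrix(phase_diff)) return(fit_drift_slice(phase_diff, region, order))
  abort_if(length(dim(phase_diff)) != 3L, "phase_diff must be a matrix or 3-D array")
  abort_if(!identical(dim(phase_diff), dim(region)), "shapes must match")
  out <- phase_diff
  for (s in seq_len(dim(phase_diff)[3]))
    out[, , s] <- fit_drift_slice(phase_diff[, , s], region[, , s], order)
  out
}

fit_drift_slice <- function(phase_diff, region, order) {
  abort_if(!identical(dim(phase_diff), dim(region)), "shapes must match")
  n <- nrow(phase_diff); m <- ncol(phase_diff)
  idx <- which(region, arr.ind = TRUE)
  n_coef <- (order + 1) * (order + 2) / 2
  abort_if(nrow(idx) < n_coef,
           sprintf("region has %d pixels but the order-%d fit needs %d",
                   nrow(idx), order, n_coef))
  X <- poly_design(idx[, 1], idx[, 2], n, m, order)
  fit <- stats::lm.fit(X, phase_diff[region])
  abort_if(fit$rank < ncol(X),
           sprintf("rank-deficient design (rank %d < %d coefficients): degenerate region geometry",
                   fit$rank, ncol(X)))
  all_idx <- which(matrix(TRUE, n, m), arr.ind = TRUE)
  surf <- poly_design(all_idx[, 1], all_idx[, 2], n, m, order) %*% fit$coefficients
  matrix(surf, n, m)
}

#' Corrected PRFS temperature-change map
#'
#' The PRFS relation inverted: `delta_T = (dphi_w - dphi_cor) / (gamma *
#' alpha * B0 * TE)` with the drift surface `dphi_cor` subtracted from the
#' wrapped phase-difference map `dphi_w` and alpha converted from ppm/degC.
#'
#' @param phase_diff phase-difference map (matrix or 3-D array), radians.
#' @param drift_surface background surface of the same shape (0 to skip
#'   correction).
#' @param acq an [acq_params()].
#' @return temperature-change map, degC, same shape as `phase_diff`.
#' @export
prfs_temperature <- function(phase_diff, drift_surface, acq = acq_params()) {
  k <- phase_per_degC(acq)
  abort_if(k == 0, "gamma * alpha * B0 * TE is zero")
  abort_if(!identical(dim(phase_diff), dim(drift_surface)) &&
             !(length(drift_surface) == 1L), "shapes must match")
  (phase_diff - drift_surface) / k
}

#' Referenceless temperature map via Goldstein unwrapping
#'
#' The motion-robust fallback method: the phase-difference map is unwrapped
#' slice-by-slice with the Goldstein branch-cut algorithm, a 4th-order spatial
#' polynomial is fitted to the unwrapped phase on the non-heated edge region as
#' the background, and the residual is converted to temperature with the PRFS
#' relation. The unwrapper's arbitrary global 2*pi*k offset is absorbed by the
#' polynomial's constant term.
#'
#' @param phase_diff matrix or 3-D array of wrapped phase differences.
#' @param edge reference-region mask of the same shape.
#' @param acq an [acq_params()].
#' @param order background polynomial degree (default 4).
#' @return temperature-change map, degC.
#' @export
referenceless_temperature <- function(phase_diff, edge, acq = acq_params(),
                                      order = 4L) {
  one_slice <- function(pd, reg) {
    uw <- goldstein_unwrap(pd)$unwrapped
    bg <- fit_drift_slice(uw, reg, order)
    (uw - bg) / phase_per_degC(acq)
  }
  k <- phase_per_degC(acq)
  abort_if(k == 0, "gamma * alpha * B0 * TE is zero")
  if (is.matrix(phase_diff)) return(one_slice(phase_diff, edge))
  out <- phase_diff
  for (s in seq_len(dim(phase_diff)[3]))
    out[, , s] <- one_slice(phase_diff[, , s], edge[, , s])
  out
}

#' Reconstruct a temperature series from a phase series
#'
#' Runs the per-frame thermometry over every post-baseline frame: wrapped
#' phase difference against the circular-mean baseline, drift correction on
#' the edge reference ring (referenced method, order-2 polynomial) or
#' referenceless Goldstein background subtraction (order-4), then PRFS
#' conversion.
#'
#' @param series a [phase_series()].
#' @param brain_mask 3-D logical array `[row, col, slice]`.
#' @param acq an [acq_params()].
#' @param method `"referenced"` (default) or `"referenceless"`.
#' @param order polynomial degree; defaults to 2 for referenced, 4 for
#'   referenceless.
#' @param edge_width_px reference ring width (default 3).
#' @param baseline_temp_C absolute baseline for downstream dosimetry.
#' @return a [temperature_series()] whose frames are the post-baseline frames.
#' @export
prfs_temperature_series <- function(series, brain_mask, acq = acq_params(),
                                    method = c("referenced", "referenceless"),
                                    order = NULL, edge_width_px = 3L,
                                    baseline_temp_C = 37) {
  method <- match.arg(method)
  if (is.null(order)) order <- if (method == "referenced") 2L else 4L
  abort_if(!identical(dim(brain_mask), dim(series$phase)[1:3]),
           "brain_mask must match the in-plane/slice dimensions")
  edge <- make_edge_reference(brain_mask, edge_width_px)
  frames <- (series$baseline_frames + 1L):dim(series$phase)[4]
  d <- c(dim(series$phase)[1:3], length(frames))
  dT <- array(0, dim = d)
  for (k in seq_along(frames)) {
    pd <- phase_difference(series, frames[k])
    dT[, , , k] <- if (method == "referenced") {
      drift <- fit_drift_polynomial(pd, edge, order)
      prfs_temperature(pd, drift, acq)
    } else {
      referenceless_temperature(pd, edge, acq, order)
    }
  }
  temperature_series(dT, series$timestamps_s[frames], series$geometry,
                     baseline_temp_C = baseline_temp_C)
}

#' ROI mean temperature curve
#'
#' Mean temperature change over a region of interest per frame, together with
#' the curve maximum ("absolute maximal temperature increase") and the time to
#' return to baseline: the first post-sonication timestamp at which the ROI
#' mean drops to `epsilon_C` or below, measured from sonication end. `NA` with
#' a warning if the curve never returns.
#'
#' @param temps a [temperature_series()].
#' @param roi nonempty logical array `[row, col, slice]`.
#' @param sonication_end_s end of heating, seconds (same clock as the series
#'   timestamps); `NULL` disables the time-to-baseline computation.
#' @param epsilon_C return-to-baseline tolerance, degC (default 1).
#' @return list of class `roi_curve`: `curve` (tibble `time_s`, `mean_dT_C`),
#'   `max_dT_C`, `time_at_max_s`, `time_to_baseline_s`.
#' @export
roi_mean_curve <- function(temps, roi, sonication_end_s = NULL, epsilon_C = 1) {
  abort_if(!inherits(temps, "temperature_series"), "temps must be a temperature_series")
  abort_if(!identical(dim(roi), dim(temps$delta_T)[1:3]),
           "roi must match the in-plane/slice dimensions")
  abort_if(!any(roi), "roi is empty")
  nf <- dim(temps$delta_T)[4]
  means <- vapply(seq_len(nf),
                  function(f) mean(arr_frame(temps$delta_T, f)[roi]), numeric(1))
  curve <- tibble::tibble(time_s = temps$timestamps_s, mean_dT_C = means)
  imax <- which.max(means)
  ttb <- NA_real_
  if (!is.null(sonication_end_s)) {
    post <- which(curve$time_s >= sonication_end_s & curve$mean_dT_C <= epsilon_C)
    if (length(post) > 0L) {
      ttb <- curve$time_s[post[1]] - sonication_end_s
    } else {
      warning("ROI mean never returned to within epsilon of baseline", call. = FALSE)
    }
  }
  structure(list(curve = curve, max_dT_C = means[imax],
                 time_at_max_s = curve$time_s[imax],
                 time_to_baseline_s = ttb, epsilon_C = epsilon_C),
            class = "roi_curve")
}

#' @export
print.roi_curve <- function(x, ...) {
  cat(sprintf("<roi_curve: %d frames, max dT %.2f degC at %.0f s, return-to-baseline %s>\n",
              nrow(x$curve), x$max_dT_C, x$time_at_max_s,
              if (is.na(x$time_to_baseline_s)) "not reached"
              else sprintf("%.0f s", x$time_to_baseline_s)))
  invisible(x)
}
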