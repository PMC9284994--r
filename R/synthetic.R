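#' Simulation configuration for a synthetic ablation acquisition
#'
#' Describes one interstitial-ultrasound sonication imaged by a multislice 2-D
#' thermometry acquisition: grid and geometry (default 256 x 256 over a 15 cm
#' field of view, 5 slices), frame timing (10 s updates), the heat source (a
#' cylindrical applicator segment of 7 mm axial extent radiating a full 360
#' degree or sectored 180 degree pattern), Pennes-bioheat tissue parameters,
#' and the phase-corruption model (2nd-order spatial drift ramping linearly in
#' time, plus additive Gaussian phase noise).
#'
#' `sonication_power_scale` maps nominal acoustic watts to the peak volumetric
#' heating rate (degC/s per W at the source centre). It was calibrated once so
#' that a 3 W, 120 s sonication peaks near an 8 degC ROI-mean rise (a
#' subacute-swine-like setting) and is fixed; it is not a per-run tuning knob.
#'
#' @param grid_shape integer pair, pixels per slice.
#' @param n_slices number of slices.
#' @param pixel_spacing_mm in-plane spacing, mm (default 150/256).
#' @param slice_thickness_mm slice thickness, mm (3 or 5 typical).
#' @param frame_interval_s seconds between frames.
#' @param n_baseline_frames leading pre-heating frames (>= 1).
#' @param sonication_power_W nominal acoustic power, watts.
#' @param sonication_duration_s heating duration, seconds (100-180 typical).
#' @param post_duration_s imaged cool-down after shutoff, seconds.
#' @param sonication_power_scale degC/s per watt at the source centre.
#' @param pattern `"SECTOR_360"` or `"SECTOR_180"`.
#' @param sector_direction_deg heated half-plane direction for SECTOR_180.
#' @param probe_position continuous (slice, row, col) position, 1-based pixel
#'   units; default grid centre.
#' @param probe_radius_mm outer radius of the applicator, mm (default 0.75);
#'   energy deposition is flat inside it.
#' @param attenuation_np_per_mm effective ultrasound intensity attenuation of
#'   brain at the operating frequency, Np/mm (default 0.07, i.e. ~0.5 Np/cm/MHz
#'   at 7 MHz for two-way absorption); the radial deposition profile is
#'   `(r0 / r) * exp(-mu * (r - r0))` outside the probe, the cylindrical
#'   spreading of an interstitial source.
#' @param source_cutoff_mm radius beyond which deposition is treated as
#'   exactly zero (default 15 mm, where the profile has fallen below ~2% of
#'   its peak and any heating is under the thermometry noise floor); keeps the
#'   far field, and in particular the edge reference region, genuinely
#'   unheated.
#' @param source_length_mm axial extent of the active element, mm (default 7).
#' @param thermal_diffusivity brain thermal diffusivity, mm^2/s (default 0.13).
#' @param perfusion_rate Pennes perfusion rate constant, 1/s (default 0.01).
#' @param baseline_temp_C absolute tissue baseline, degC (default 37).
#' @param drift_coeffs length-6 numeric: 2nd-order polynomial coefficients
#'   (1, x, y, x^2, xy, y^2 on normalised coordinates) of the field drift at
#'   the final frame, radians; ramps linearly from zero.
#' @param noise_sd_rad additive Gaussian phase noise SD, radians.
#' @param dt_s optional forced solver step, seconds; must satisfy the
#'   explicit-scheme stability bound or an error is raised.
#' @param seed integer RNG seed; identical seed + config give bit-identical
#'   output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(grid_shape = c(256L, 256L), n_slices = 5L,
                       pixel_spacing_mm = 150 / 256, slice_thickness_mm = 5,
                       frame_interval_s = 10, n_baseline_frames = 2L,
                       sonication_power_W = 3, sonication_duration_s = 120,
                       post_duration_s = 180,
                       sonication_power_scale = 0.30,
                       pattern = c("SECTOR_360", "SECTOR_180"),
                       sector_direction_deg = 0,
                       probe_position = NULL,
                       probe_radius_mm = 0.75, attenuation_np_per_mm = 0.07,
                       source_cutoff_mm = 15, source_length_mm = 7,
                       thermal_diffusivity = 0.13, perfusion_rate = 0.008,
                       baseline_temp_C = 37,
                       drift_coeffs = rep(0, 6), noise_sd_rad = 0,
                       dt_s = NULL, seed = 1L) {
  pattern <- match.arg(pattern)
  grid_shape <- rep_len(as.integer(grid_shape), 2L)
  abort_if(any(grid_shape < 4L) || n_slices < 1L, "grid too small")
  abort_if(frame_interval_s <= 0, "frame_interval_s must be positive")
  abort_if(noise_sd_rad < 0, "noise_sd_rad must be nonnegative")
  abort_if(sonication_duration_s <= 0 || post_duration_s < 0,
           "durations must be positive")
  abort_if(length(drift_coeffs) != 6L, "drift_coeffs must have length 6")
  pixel_spacing_mm <- rep_len(as.numeric(pixel_spacing_mm), 2L)
  if (is.null(probe_position))
    probe_position <- c((n_slices + 1) / 2, (grid_shape[1] + 1) / 2,
                        (grid_shape[2] + 1) / 2)
  structure(list(
    grid_shape = grid_shape, n_slices = as.integer(n_slices),
    pixel_spacing_mm = pixel_spacing_mm,
    slice_thickness_mm = slice_thickness_mm,
    frame_interval_s = frame_interval_s,
    n_baseline_frames = as.integer(n_baseline_frames),
    sonication_power_W = sonication_power_W,
    sonication_duration_s = sonication_duration_s,
    post_duration_s = post_duration_s,
    sonication_power_scale = sonication_power_scale,
    pattern = pattern, sector_direction_deg = sector_direction_deg,
    probe_position = as.numeric(probe_position),
    probe_radius_mm = probe_radius_mm,
    attenuation_np_per_mm = attenuation_np_per_mm,
    source_cutoff_mm = source_cutoff_mm,
    source_length_mm = source_length_mm,
    thermal_diffusivity = thermal_diffusivity,
    perfusion_rate = perfusion_rate, baseline_temp_C = baseline_temp_C,
    drift_coeffs = as.numeric(drift_coeffs), noise_sd_rad = noise_sd_rad,
    dt_s = dt_s, seed = as.integer(seed)), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config: %dx%dx%d, %g W %s for %g s, %g s frames, seed %d>\n",
              x$grid_shape[1], x$grid_shape[2], x$n_slices,
              x$sonication_power_W, x$pattern, x$sonication_duration_s,
              x$frame_interval_s, x$seed))
  invisible(x)
}

sim_geometry <- function(config) {
  image_geometry(config$pixel_spacing_mm, config$slice_thickness_mm)
}

#' Sonication on/off times of a configured acquisition
#'
#' Heating starts after the baseline frames and runs for the configured
#' duration.
#'
#' @param config a [sim_config()].
#' @return named numeric `c(on =, off =)`, seconds on the frame clock.
#' @export
sonication_window <- function(config) {
  on <- config$n_baseline_frames * config$frame_interval_s
  c(on = on, off = on + config$sonication_duration_s)
}

# volumetric heating-rate field, degC/s, at full power
source_field <- function(config) {
  n <- config$grid_shape; ns <- config$n_slices
  sp <- config$pixel_spacing_mm
  xr <- (seq_len(n[1]) - config$probe_position[2]) * sp[1]
  yc <- (seq_len(n[2]) - config$probe_position[3]) * sp[2]
  r <- sqrt(outer(xr^2, yc^2, `+`))
  r0 <- config$probe_radius_mm
  mu <- config$attenuation_np_per_mm
  radial <- ifelse(r <= r0, 1, (r0 / pmax(r, r0)) * exp(-mu * (r - r0)))
  radial[r > config$source_cutoff_mm] <- 0
  if (config$pattern == "SECTOR_180") {
    # all the acoustic power exits through the half-cylinder window, so the
    # heated sector sees twice the 360-degree surface intensity
    dir <- config$sector_direction_deg * pi / 180
    theta <- atan2(outer(rep(1, n[1]), yc), outer(xr, rep(1, n[2])))
    radial <- 2 * radial * (cos(theta - dir) >= 0)
  }
  zs <- (seq_len(ns) - config$probe_position[1]) * config$slice_thickness_mm
  axial <- as.numeric(abs(zs) <= config$source_length_mm / 2)
  amp <- config$sonication_power_scale * config$sonication_power_W
  q <- array(0, dim = c(n[1], n[2], ns))
  for (s in seq_len(ns)) q[, , s] <- amp * radial * axial[s]
  q
}

# anisotropic 7-point Laplacian with zero-flux (edge-replicated) boundaries
laplacian3d <- function(T, h) {
  d <- dim(T)
  ixp <- c(2:d[1], d[1]); ixm <- c(1, 1:(d[1] - 1))
  jyp <- c(2:d[2], d[2]); jym <- c(1, 1:(d[2] - 1))
  out <- (T[ixp, , , drop = FALSE] + T[ixm, , , drop = FALSE] - 2 * T) / h[1]^2 +
         (T[, jyp, , drop = FALSE] + T[, jym, , drop = FALSE] - 2 * T) / h[2]^2
  if (d[3] > 1L) {
    kzp <- c(2:d[3], d[3]); kzm <- c(1, 1:(d[3] - 1))
    out <- out + (T[, , kzp, drop = FALSE] + T[, , kzm, drop = FALSE] - 2 * T) / h[3]^2
  }
  out
}

#' Simulate the ground-truth temperature series
#'
#' Explicit finite-difference solution of a Pennes-style bioheat equation for
#' the temperature change `dT` above baseline,
#' `d(dT)/dt = kappa * lap(dT) - w * dT + Q(x, t)`,
#' on the configured grid with insulated (zero-flux) boundaries. `Q` is a
#' cylindrical Gaussian-profile source at the probe position, 7 mm axial
#' extent, masked to a half-plane for the 180 degree sector pattern, active
#' only during the sonication window. The solver sub-steps between frames to
#' satisfy the explicit-scheme stability bound; a user-forced step that
#' violates the bound raises an error naming it.
#'
#' @param config a [sim_config()].
#' @return a [temperature_series()] sampled at the frame interval (frame 1 at
#'   t = 0 is a pre-heating baseline), with the config attached as attribute
#'   `sim_config`.
#' @export
simulate_temperature <- function(config) {
  abort_if(!inherits(config, "sim_config"), "config must be a sim_config")
  h <- c(config$pixel_spacing_mm, config$slice_thickness_mm)
  kappa <- config$thermal_diffusivity
  w <- config$perfusion_rate
  dt_max <- 1 / (2 * kappa * sum(1 / h^2) + w)
  if (!is.null(config$dt_s)) {
    abort_if(config$dt_s > dt_max,
             sprintf("dt_s = %.4g s violates the explicit stability bound dt <= 1/(2*kappa*sum(1/h^2) + w) = %.4g s",
                     config$dt_s, dt_max))
    dt_target <- config$dt_s
  } else {
    dt_target <- 0.9 * dt_max
  }
  n_sub <- max(1L, ceiling(config$frame_interval_s / dt_target))
  dt <- config$frame_interval_s / n_sub

  win <- sonication_window(config)
  n_frames <- config$n_baseline_frames +
    ceiling((config$sonication_duration_s + config$post_duration_s) /
              config$frame_interval_s)
  times <- (seq_len(n_frames) - 1) * config$frame_interval_s

  q <- source_field(config)
  T <- array(0, dim = dim(q))
  frames <- array(0, dim = c(dim(q), n_frames))
  for (f in 2:n_frames) {
    t0 <- times[f - 1]
    for (s in seq_len(n_sub)) {
      t_now <- t0 + (s - 1) * dt
      heating <- t_now >= win["on"] && t_now < win["off"]
      T <- T + dt * (kappa * laplacian3d(T, h) - w * T + if (heating) q else 0)
    }
    frames[, , , f] <- T
  }
  out <- temperature_series(frames, times, sim_geometry(config),
                            baseline_temp_C = config$baseline_temp_C)
  attr(out, "sim_config") <- config
  out
}

#' Simulate ground truth: temperature, dose, necrosis
#'
#' Convenience wrapper running [simulate_temperature()] and accumulating the
#' true CEM43 dose, necrosis mask and necrosis volume at the configured
#' threshold.
#'
#' @param config a [sim_config()].
#' @param params a [dose_params()]; its baseline is taken from the config.
#' @return list of class `ground_truth`: `temperature`
#'   ([temperature_series()]), `dose` ([dose_map()]), `necrosis_mask` (logical
#'   array), `necrosis_volume_cm3`, `config`, `params`.
#' @export
simulate_ground_truth <- function(config, params = NULL) {
  if (is.null(params)) params <- dose_params(baseline_temp_C = config$baseline_temp_C)
  temps <- simulate_temperature(config)
  dose <- accumulate_cem43(temps, params)
  mask <- dose$cem43 > params$threshold_CEM
  structure(list(temperature = temps, dose = dose, necrosis_mask = mask,
                 necrosis_volume_cm3 = sum(mask) * voxel_volume_cm3(dose$geometry),
                 config = config, params = params),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth: peak dT %.2f degC, necrosis %.3f cm^3 at CEM43 > %g>\n",
              max(x$temperature$delta_T), x$necrosis_volume_cm3,
              x$params$threshold_CEM))
  invisible(x)
}

# drift surface (order-2 polynomial on normalised coords) at ramp fraction f
drift_surface <- function(coeffs, n, m, frac) {
  idx <- which(matrix(TRUE, n, m), arr.ind = TRUE)
  matrix(poly_design(idx[, 1], idx[, 2], n, m, 2L) %*% (coeffs * frac), n, m)
}

#' Render a wrapped-phase series from a temperature series
#'
#' Forward model of the PRFS acquisition: per frame, wrapped phase
#' `wrap(gamma * alpha * B0 * TE * dT + drift(t) + noise)`, where the drift is
#' a 2nd-order spatial polynomial whose coefficients ramp linearly from zero
#' to `drift_coeffs` at the final frame, and the noise is additive Gaussian on
#' phase (the high-SNR limit of Rician magnitude noise). Frame timing,
#' baseline frames and the corruption defaults come from the simulation
#' config attached to `truth`.
#'
#' @param truth a [temperature_series()] from [simulate_temperature()] (or any
#'   temperature series plus an explicit `baseline_frames`).
#' @param acq an [acq_params()].
#' @param drift_coeffs,noise_sd_rad,seed override the config's values.
#' @param background_phase optional static anatomical phase array
#'   `[row, col, slice]` added to every frame (default 0).
#' @param baseline_frames override when `truth` carries no config.
#' @return a [phase_series()].
#' @export
render_phase_series <- function(truth, acq = acq_params(), drift_coeffs = NULL,
                                noise_sd_rad = NULL, seed = NULL,
                                background_phase = NULL,
                                baseline_frames = NULL) {
  abort_if(!inherits(truth, "temperature_series"), "truth must be a temperature_series")
  cfg <- attr(truth, "sim_config")
  if (is.null(drift_coeffs)) drift_coeffs <- if (!is.null(cfg)) cfg$drift_coeffs else rep(0, 6)
  if (is.null(noise_sd_rad)) noise_sd_rad <- if (!is.null(cfg)) cfg$noise_sd_rad else 0
  if (is.null(seed)) seed <- if (!is.null(cfg)) cfg$seed else 1L
  if (is.null(baseline_frames))
    baseline_frames <- if (!is.null(cfg)) cfg$n_baseline_frames else 1L
  k <- phase_per_degC(acq)
  abort_if(k == 0, "gamma * alpha * B0 * TE is zero")
  d <- dim(truth$delta_T)
  t_final <- truth$timestamps_s[d[4]]
  if (is.null(background_phase)) background_phase <- array(0, dim = d[1:3])
  phase <- array(0, dim = d)
  noise <- if (noise_sd_rad > 0) {
    withr::with_seed(seed, array(stats::rnorm(prod(d), sd = noise_sd_rad), dim = d))
  } else {
    array(0, dim = d)
  }
  for (f in seq_len(d[4])) {
    frac <- if (t_final > 0) truth$timestamps_s[f] / t_final else 0
    dr <- drift_surface(drift_coeffs, d[1], d[2], frac)
    for (s in seq_len(d[3])) {
      phase[, , s, f] <- wrap_phase(background_phase[, , s] +
                                      k * truth$delta_T[, , s, f] +
                                      dr + noise[, , s, f])
    }
  }
  phase_series(phase, truth$timestamps_s, truth$geometry,
               baseline_frames = baseline_frames)
}

#' Synthesize traced histology sections from ground truth
#'
#' Emulates postmortem sectioning and planimetry: the true necrosis mask is
#' resampled onto contiguous coronal slabs of the requested thickness (exact
#' partial-volume overlap between imaging slices and slabs, so the noise-free
#' section volumes sum to the true necrosis volume), and per-slab lesion areas
#' are optionally perturbed by multiplicative Gaussian noise emulating tracing
#' variability. All emitted sections are through-lesions (`full_thickness =
#' TRUE`); partial-thickness tables are built by hand where needed.
#'
#' @param truth a `ground_truth` from [simulate_ground_truth()].
#' @param slice_thickness_mm slab thickness, mm (default 5).
#' @param observer_noise_frac SD of the multiplicative area noise (default 0).
#' @param seed RNG seed.
#' @return a [histology_sections()] table.
#' @export
synthesize_histology <- function(truth, slice_thickness_mm = 5,
                                 observer_noise_frac = 0, seed = 1L) {
  abort_if(!inherits(truth, "ground_truth"), "truth must be a ground_truth")
  abort_if(observer_noise_frac < 0, "observer_noise_frac must be nonnegative")
  mask <- truth$necrosis_mask
  geo <- truth$dose$geometry
  dz <- geo$slice_thickness_mm
  px_cm2 <- prod(geo$pixel_spacing_mm) / 100
  ns <- dim(mask)[3]
  areas_slice <- vapply(seq_len(ns), function(s) sum(mask[, , s]) * px_cm2,
                        numeric(1))
  h <- slice_thickness_mm
  n_sect <- ceiling(ns * dz / h)
  vol_sect <- numeric(n_sect)
  for (s in seq_len(ns)) {
    z0 <- (s - 1) * dz; z1 <- s * dz
    for (t in seq_len(n_sect)) {
      ov <- max(0, min(z1, t * h) - max(z0, (t - 1) * h))
      if (ov > 0) vol_sect[t] <- vol_sect[t] + areas_slice[s] * ov / 10
    }
  }
  areas <- vol_sect / (h / 10)
  if (observer_noise_frac > 0) {
    areas <- withr::with_seed(seed,
      pmax(0, areas * (1 + stats::rnorm(n_sect, sd = observer_noise_frac))))
  }
  histology_sections(seq_len(n_sect), areas, full_thickness = TRUE,
                     slice_thickness_cm = h / 10)
}

#' Default heating ROI around the probe
#'
#' The analysis ROI a user would draw over the visible heating: an in-plane
#' disk of the given radius centred on the probe, on the slices covered by the
#' active element.
#'
#' @param config a [sim_config()].
#' @param radius_mm disk radius, mm (default 3).
#' @return logical array `[row, col, slice]`.
#' @export
default_heating_roi <- function(config, radius_mm = 3) {
  n <- config$grid_shape; ns <- config$n_slices
  sp <- config$pixel_spacing_mm
  xr <- (seq_len(n[1]) - config$probe_position[2]) * sp[1]
  yc <- (seq_len(n[2]) - config$probe_position[3]) * sp[2]
  disk <- outer(xr^2, yc^2, `+`) <= radius_mm^2
  zs <- (seq_len(ns) - config$probe_position[1]) * config$slice_thickness_mm
  roi <- array(FALSE, dim = c(n[1], n[2], ns))
  for (s in which(abs(zs) <= config$source_length_mm / 2)) roi[, , s] <- disk
  roi
}

#' Default brain mask for simulated acquisitions
#'
#' An elliptical "visible brain" occupying most of the field of view, giving
#' the thermometry an outer edge to build its reference ring on.
#'
#' @param config a [sim_config()].
#' @param fraction semi-axes as a fraction of the half field of view.
#' @return logical array `[row, col, slice]`.
#' @export
default_brain_mask <- function(config, fraction = 0.8) {
  n <- config$grid_shape
  ci <- (n[1] + 1) / 2; cj <- (n[2] + 1) / 2
  u <- (seq_len(n[1]) - ci) / (fraction * n[1] / 2)
  v <- (seq_len(n[2]) - cj) / (fraction * n[2] / 2)
  disk <- outer(u^2, v^2, `+`) <= 1
  array(rep(disk, config$n_slices), dim = c(n[1], n[2], config$n_slices))
}
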