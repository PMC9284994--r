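# small, fast simulation configs used across the suite

small_config <- function(...) {
  defaults <- list(grid_shape = c(48L, 48L), pixel_spacing_mm = 150 / 48,
                   n_slices = 3L, frame_interval_s = 10,
                   n_baseline_frames = 2L, post_duration_s = 120, seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# a constant-temperature series: T_abs held at temp_C for total_min minutes
constant_temp_series <- function(temp_C, total_min, baseline_C = 37,
                                 step_s = 60, nx = 2, ny = 2, ns = 1) {
  times <- seq(0, total_min * 60, by = step_s)
  dT <- array(temp_C - baseline_C, dim = c(nx, ny, ns, length(times)))
  temperature_series(dT, times, image_geometry(c(1, 1), 5),
                     baseline_temp_C = baseline_C)
}

# independent brute-force Sapareto-Dewey accumulation (per-pixel loop)
cem43_oracle <- function(temps, R_lo = 0.25, R_hi = 0.5, ref = 43) {
  d <- dim(temps$delta_T)
  out <- array(0, dim = d[1:3])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (s in seq_len(d[3])) {
    acc <- 0
    for (f in seq_len(d[4] - 1)) {
      t_avg <- temps$baseline_temp_C +
        (temps$delta_T[i, j, s, f] + temps$delta_T[i, j, s, f + 1]) / 2
      r <- if (t_avg >= ref) R_hi else R_lo
      acc <- acc + r^(ref - t_avg) *
        (temps$timestamps_s[f + 1] - temps$timestamps_s[f]) / 60
    }
    out[i, j, s] <- acc
  }
  out
}

# brute-force edge ring: pixel is in the ring iff it is in the mask and its
# (2w+1)^2 Chebyshev neighbourhood is not fully inside the mask
edge_ring_oracle <- function(mask, width) {
  n <- nrow(mask); m <- ncol(mask)
  out <- matrix(FALSE, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (!mask[i, j]) next
    fully_inside <- TRUE
    for (di in -width:width) for (dj in -width:width) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > n || jj < 1 || jj > m || !mask[ii, jj]) {
        fully_inside <- FALSE
      }
    }
    out[i, j] <- !fully_inside
  }
  out
}
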