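acq <- acq_params()  # 3 T, TE 13.2 ms, alpha -0.01 ppm/degC

test_that("phase_difference wraps correctly and matches the complex-ratio oracle", {
  geo <- image_geometry(c(1, 1), 5)
  mk <- function(base, frame) {
    ph <- array(0, dim = c(4, 4, 1, 2))
    ph[, , , 1] <- base; ph[, , , 2] <- frame
    phase_series(ph, c(0, 10), geo, baseline_frames = 1L)
  }
  # identical frames -> zero map
  expect_equal(phase_difference(mk(0.7, 0.7), 2), array(0, dim = c(4, 4, 1)))
  # wrap-around: baseline 3.0, frame -3.0 -> +0.283, not -6.0
  d <- phase_difference(mk(3.0, -3.0), 2)
  expect_equal(d[1, 1, 1], 2 * pi - 6, tolerance = 1e-12)
  # random wrapped inputs agree with the per-pixel Arg(exp(i dphi)) oracle
  set.seed(17)
  p0 <- array(runif(4 * 4, -pi, pi), dim = c(4, 4))
  p1 <- array(runif(4 * 4, -pi, pi), dim = c(4, 4))
  got <- phase_difference(mk(p0, p1), 2)
  oracle <- Arg(exp(1i * (p1 - p0)))
  expect_equal(got[, , 1], oracle, tolerance = 1e-12)
  expect_error(phase_difference(mk(0, 0), 1), "frame")
  expect_error(phase_difference(mk(0, 0), 3), "frame")
})

test_that("baseline is the circular mean of the pre-heating frames", {
  geo <- image_geometry(c(1, 1), 5)
  ph <- array(0, dim = c(2, 2, 1, 3))
  ph[, , , 1] <- 3.1; ph[, , , 2] <- -3.1   # circular mean is pi, not 0
  ph[, , , 3] <- -3.0
  s <- phase_series(ph, c(0, 5, 10), geo, baseline_frames = 2L)
  d <- phase_difference(s, 3)
  expect_equal(d[1, 1, 1], wrap_phase(-3.0 - pi), tolerance = 1e-9)
})

test_that("edge reference ring equals the brute-force erosion oracle", {
  # full-grid mask, width 3: the outer 3 shells
  full <- matrix(TRUE, 12, 12)
  ring <- make_edge_reference(full, 3)
  expect_equal(ring, edge_ring_oracle(full, 3))
  expect_false(ring[6, 6])
  expect_true(all(ring[1, ]))
  # disk mask
  n <- 41
  disk <- outer((1:n - 21)^2, (1:n - 21)^2, `+`) <= 20^2
  expect_equal(make_edge_reference(disk, 3), edge_ring_oracle(disk, 3))
  # errors: zero width, over-erosion
  expect_error(make_edge_reference(disk, 0), "width")
  small <- outer((1:9 - 5)^2, (1:9 - 5)^2, `+`) <= 3^2
  expect_error(make_edge_reference(small, 5), "eroded to empty")
})

test_that("drift polynomial fit recovers exact polynomials and rejects degenerate regions", {
  n <- 32
  ij <- expand.grid(i = 1:n, j = 1:n)
  x <- 2 * (ij$i - 1) / (n - 1) - 1
  y <- 2 * (ij$j - 1) / (n - 1) - 1
  truth <- matrix(0.3 - 0.2 * x + 0.15 * y + 0.08 * x^2 - 0.05 * x * y + 0.02 * y^2,
                  n, n)
  ring <- make_edge_reference(matrix(TRUE, n, n), 3)
  surf <- fit_drift_polynomial(truth, ring, order = 2)
  expect_lt(max(abs(surf - truth)), 1e-8)   # exact recovery everywhere
  # constant input -> constant surface
  expect_lt(max(abs(fit_drift_polynomial(matrix(0.7, n, n), ring, 2) - 0.7)), 1e-10)
  # a single-row region cannot identify a 2-D quadratic
  degen <- matrix(FALSE, n, n); degen[5, ] <- TRUE
  expect_error(fit_drift_polynomial(truth, degen, 2), "rank-deficient")
  # too few pixels for the coefficient count
  tiny <- matrix(FALSE, n, n); tiny[3, 3] <- TRUE
  expect_error(fit_drift_polynomial(truth, tiny, 2), "needs")
})

test_that("prfs_temperature inverts the PRFS relation and is linear", {
  z <- array(0, dim = c(3, 3, 1))
  expect_equal(prfs_temperature(z, z, acq), z)
  # -0.10595 rad at 3 T / 13.2 ms / -0.01 ppm -> +1.000 degC
  pd <- z; pd[] <- -0.10595
  dT <- prfs_temperature(pd, z, acq)
  expect_equal(dT[1, 1, 1], 1.0, tolerance = 1e-3)
  # exact inverse of the forward factor
  k <- acq$gamma_rad_s_T * acq$alpha_ppm_per_C * 1e-6 * acq$B0 * acq$TE
  pd[] <- k * 2.5
  expect_equal(prfs_temperature(pd, z, acq)[2, 2, 1], 2.5, tolerance = 1e-12)
  # linearity in the corrected phase
  set.seed(19)
  pd[] <- rnorm(9)
  expect_equal(prfs_temperature(3 * pd, z, acq), 3 * prfs_temperature(pd, z, acq),
               tolerance = 1e-12)
  expect_error(prfs_temperature(pd, z, acq_params(alpha_ppm_per_C = NA)), "alpha")
})

test_that("simulator round trip: noise-free referenced recon matches ground truth", {
  cfg <- small_config(noise_sd_rad = 0, drift_coeffs = rep(0, 6))
  temps_true <- simulate_temperature(cfg)
  series <- render_phase_series(temps_true)
  mask <- default_brain_mask(cfg)
  est <- prfs_temperature_series(series, mask)
  frames <- (cfg$n_baseline_frames + 1):dim(temps_true$delta_T)[4]
  expect_lt(max(abs(est$delta_T - temps_true$delta_T[, , , frames])), 1e-6)
})

test_that("referenced correction rejects quadratic drift down to the noise floor", {
  drift <- c(0.12, 0.06, -0.05, 0.03, -0.02, 0.04)
  cfg_noise <- small_config(sonication_power_W = 0, noise_sd_rad = 0.02,
                            drift_coeffs = rep(0, 6))
  cfg_both <- small_config(sonication_power_W = 0, noise_sd_rad = 0.02,
                           drift_coeffs = drift)
  temps0 <- simulate_temperature(cfg_noise)   # identically zero field
  mask <- default_brain_mask(cfg_noise)
  sd_brain <- function(cfg) {
    est <- prfs_temperature_series(render_phase_series(simulate_temperature(cfg)),
                                   mask)
    mean(apply(est$delta_T, 4, function(m) sd(m[mask])))
  }
  expect_lt(sd_brain(cfg_both), sd_brain(cfg_noise) * 1.05)
})

test_that("order 2 beats orders 1 and 3 on data with quadratic drift", {
  drift <- c(0.12, 0.06, -0.05, 0.03, -0.02, 0.04)
  cfg <- small_config(sonication_power_W = 0, noise_sd_rad = 0.03,
                      drift_coeffs = drift)
  series <- render_phase_series(simulate_temperature(cfg))
  mask <- default_brain_mask(cfg)
  sd_order <- function(ord) {
    est <- prfs_temperature_series(series, mask, order = ord)
    mean(apply(est$delta_T, 4, function(m) sd(m[mask])))
  }
  s1 <- sd_order(1); s2 <- sd_order(2); s3 <- sd_order(3)
  expect_lt(s2, s1)           # underfit leaves drift in the maps
  expect_lte(s2, s3 * 1.02)   # overfit cannot do materially better
})

test_that("referenceless method absorbs a smooth background and agrees with referenced", {
  # zero heating, order <= 4 background, noise-free -> dT identically 0
  n <- 48
  ij <- expand.grid(i = 1:n, j = 1:n)
  x <- 2 * (ij$i - 1) / (n - 1) - 1
  y <- 2 * (ij$j - 1) / (n - 1) - 1
  bg <- matrix(1.5 + 2.2 * x - 1.1 * y + 0.9 * x^2 * y + 0.4 * y^4, n, n)
  mask <- outer((1:n - (n + 1) / 2)^2, (1:n - (n + 1) / 2)^2, `+`) <= (0.45 * n)^2
  edge <- make_edge_reference(mask, 3)
  dT <- referenceless_temperature(wrap_phase(bg), edge, acq, order = 4)
  expect_lt(max(abs(dT[mask])), 1e-6)
  # an order-4 background is NOT absorbed by an order-2 fit (underfit detected)
  dT2 <- referenceless_temperature(wrap_phase(bg), edge, acq, order = 2)
  expect_gt(sd(dT2[mask]), 10 * sd(dT[mask]) + 0.01)
  # on simulator data the two methods agree inside the heating ROI
  cfg <- small_config(noise_sd_rad = 0, drift_coeffs = c(0.1, 0.05, -0.04, 0, 0, 0))
  truth <- simulate_temperature(cfg)
  series <- render_phase_series(truth)
  bmask <- default_brain_mask(cfg)
  ref <- prfs_temperature_series(series, bmask, method = "referenced")
  noref <- prfs_temperature_series(series, bmask, method = "referenceless")
  roi <- default_heating_roi(cfg, 5)
  f_peak <- which.max(apply(ref$delta_T, 4, max))
  expect_lt(max(abs(ref$delta_T[, , , f_peak][roi] - noref$delta_T[, , , f_peak][roi])),
            0.5)
})

test_that("roi_mean_curve reports mean, max and time-to-baseline per contract", {
  geo <- image_geometry(c(1, 1), 5)
  dT <- array(0, dim = c(4, 4, 1, 5))
  roi <- array(FALSE, dim = c(4, 4, 1)); roi[2:3, 2:3, 1] <- TRUE
  dT[2:3, 2:3, 1, ] <- rep(c(0, 5, 5, 0.5, 0.2), each = 4)
  temps <- temperature_series(dT, seq(0, 40, by = 10), geo)
  rc <- roi_mean_curve(temps, roi, sonication_end_s = 20)
  expect_equal(rc$curve$mean_dT_C, c(0, 5, 5, 0.5, 0.2))
  expect_equal(rc$max_dT_C, 5)
  expect_equal(rc$time_to_baseline_s, 10)   # first frame at/below 1 degC after 20 s
  # never returns -> NA with a warning
  dT[2:3, 2:3, 1, ] <- 5
  hot <- temperature_series(dT, seq(0, 40, by = 10), geo)
  expect_warning(rc2 <- roi_mean_curve(hot, roi, sonication_end_s = 20),
                 "never returned")
  expect_true(is.na(rc2$time_to_baseline_s))
  expect_error(roi_mean_curve(temps, array(FALSE, dim = c(4, 4, 1))), "empty")
})
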