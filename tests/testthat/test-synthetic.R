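test_that("zero source power leaves the field identically zero", {
  cfg <- small_config(sonication_power_W = 0)
  temps <- simulate_temperature(cfg)
  expect_equal(max(abs(temps$delta_T)), 0)
})

test_that("the simulator is deterministic and enforces its stability bound", {
  cfg <- small_config(noise_sd_rad = 0.05, seed = 7L)
  a <- render_phase_series(simulate_temperature(cfg))
  b <- render_phase_series(simulate_temperature(cfg))
  expect_identical(a$phase, b$phase)
  # a different seed changes the noise
  cfg2 <- small_config(noise_sd_rad = 0.05, seed = 8L)
  expect_false(identical(render_phase_series(simulate_temperature(cfg2))$phase,
                         a$phase))
  # explicit-step stability: a too-large forced step errors, naming the bound
  expect_error(simulate_temperature(small_config(dt_s = 1e6)),
               "stability bound")
})

test_that("insulated boundaries conserve heat after shutoff when perfusion is off", {
  cfg <- small_config(perfusion_rate = 0, sonication_duration_s = 30,
                      post_duration_s = 120)
  temps <- simulate_temperature(cfg)
  off_frame <- cfg$n_baseline_frames + ceiling(30 / cfg$frame_interval_s) + 1L
  sums <- apply(temps$delta_T, 4, sum)
  nf <- length(sums)
  expect_gt(sums[off_frame], 0)
  rel <- abs(sums[nf] - sums[off_frame]) / sums[off_frame]
  expect_lt(rel, 1e-6)
})

test_that("the 180-degree sector leaves the far unheated side cold", {
  cfg <- small_config(pattern = "SECTOR_180", sector_direction_deg = 0)
  temps <- simulate_temperature(cfg)
  peak_map <- apply(temps$delta_T, 1:3, max)
  global_peak <- max(peak_map)
  # heated half-plane is x >= 0 (rows past the probe); take pixels strictly on
  # the other side and > 3 pixels from the probe
  pr <- cfg$probe_position[2]; pc <- cfg$probe_position[3]
  cold <- which(outer(seq_len(cfg$grid_shape[1]) - pr,
                      seq_len(cfg$grid_shape[2]) - pc,
                      function(di, dj) di < -3 & sqrt(di^2 + dj^2) > 3),
                arr.ind = TRUE)
  cold_peaks <- peak_map[cbind(cold, rep(2L, nrow(cold)))]
  expect_lt(max(cold_peaks), 0.10 * global_peak)
})

test_that("ground-truth dose is monotone over time and consistent with its mask", {
  cfg <- small_config()
  gt <- simulate_ground_truth(cfg)
  expect_identical(gt$necrosis_mask, gt$dose$cem43 > gt$params$threshold_CEM)
  expect_equal(gt$necrosis_volume_cm3,
               sum(gt$necrosis_mask) * prod(cfg$pixel_spacing_mm) *
                 cfg$slice_thickness_mm / 1000, tolerance = 1e-12)
  # dose accumulated over a prefix never exceeds the full accumulation
  temps <- gt$temperature
  nf <- dim(temps$delta_T)[4]
  prefix <- temperature_series(temps$delta_T[, , , 1:(nf - 4), drop = FALSE],
                               temps$timestamps_s[1:(nf - 4)], temps$geometry,
                               baseline_temp_C = temps$baseline_temp_C)
  expect_true(all(accumulate_cem43(prefix)$cem43 <= gt$dose$cem43 + 1e-12))
})

test_that("phase rendering applies the PRFS factor, wrapping and baseline frames", {
  geo <- image_geometry(c(1, 1), 5)
  dT <- array(0, dim = c(4, 4, 1, 3))
  dT[, , , 3] <- 1                            # 1 degC uniform on the last frame
  truth <- temperature_series(dT, c(0, 10, 20), geo)
  s <- render_phase_series(truth, baseline_frames = 2L)
  # all pre-heating frames identical to baseline when drift and noise are off
  expect_equal(s$phase[, , , 1], s$phase[, , , 2])
  # 1 degC at 3 T, 13.2 ms, -0.01 ppm/degC: shift ~ -0.1060 rad
  shift <- s$phase[1, 1, 1, 3] - s$phase[1, 1, 1, 1]
  expect_equal(shift, -0.10594, tolerance = 1e-4)
  # wrapping: an injected +4 rad background lands at 4 - 2*pi
  bg <- array(4, dim = c(4, 4, 1))
  s2 <- render_phase_series(truth, background_phase = bg, baseline_frames = 2L)
  expect_equal(s2$phase[1, 1, 1, 1], 4 - 2 * pi, tolerance = 1e-12)
})

test_that("synthetic histology reproduces the ground-truth volume when noise-free", {
  # a hot 6 W / 180 s run so the necrotic zone spans several coarse voxels
  cfg <- small_config(sonication_power_W = 6, sonication_duration_s = 180)
  gt <- simulate_ground_truth(cfg)
  expect_gt(gt$necrosis_volume_cm3, 0)
  sect <- synthesize_histology(gt, slice_thickness_mm = 5, observer_noise_frac = 0)
  # noise-free sectioning is volume-preserving to the resampling quantum
  vox <- prod(cfg$pixel_spacing_mm) * cfg$slice_thickness_mm / 1000
  expect_lt(abs(histology_volume(sect) - gt$necrosis_volume_cm3), vox + 1e-12)
  # an empty mask gives all-zero areas
  gt0 <- gt
  gt0$necrosis_mask[] <- FALSE
  sect0 <- synthesize_histology(gt0)
  expect_true(all(sect0$area_cm2 == 0))
  # tracing noise perturbs areas but keeps volumes within ~15%
  s1 <- synthesize_histology(gt, observer_noise_frac = 0.05, seed = 1)
  s2 <- synthesize_histology(gt, observer_noise_frac = 0.05, seed = 2)
  expect_false(identical(s1$area_cm2, s2$area_cm2))
  v1 <- histology_volume(s1); v2 <- histology_volume(s2)
  expect_lt(abs(v1 - v2) / max(v1, v2), 0.15)
})

test_that("a Swine-5-like sonication lands in the reported thermal envelope", {
  # 3 W for 120 s with the calibrated power scale: ROI-mean peak near 8 degC
  # (8 +/- 4 band) and return to baseline within the reported 90-180 s
  cfg <- sim_config(grid_shape = c(96L, 96L), pixel_spacing_mm = 150 / 96,
                    n_slices = 5L, sonication_power_W = 3,
                    sonication_duration_s = 120)
  temps <- simulate_temperature(cfg)
  roi <- default_heating_roi(cfg, 3)
  rc <- roi_mean_curve(temps, roi,
                       sonication_end_s = unname(sonication_window(cfg)["off"]))
  expect_gt(rc$max_dT_C, 4)
  expect_lt(rc$max_dT_C, 12)
  expect_gte(rc$time_to_baseline_s, 60)
  expect_lte(rc$time_to_baseline_s, 180)
})
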