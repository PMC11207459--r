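test_that("phantom trajectories echo the configuration and are deterministic", {
  ph1 <- make_breathing_phantom(phantom_config(duration_s = 20), seed = 0)
  ph2 <- make_breathing_phantom(phantom_config(duration_s = 20), seed = 0)
  expect_identical(ph1$trajectory, ph2$trajectory)

  tr <- ph1$trajectory
  expect_true(all(diff(tr$times) > 0))
  expect_true(all(c("cough", "deep_breath") %in% tr$event_labels))
  expect_equal(length(tr$resp_displacement), length(tr$times))
  expect_equal(length(tr$event_labels), length(tr$times))

  ## normal-breathing excursion close to the configured 10 mm peak-to-peak
  normal <- tr$event_labels == "normal"
  ptp <- diff(range(tr$resp_displacement[normal]))
  expect_gt(ptp, 7); expect_lt(ptp, 14)

  ## zero-amplitude phantom has a (drift-only) flat respiratory trace
  ph0 <- make_breathing_phantom(quiet_cfg(resp_amplitude_mm = 0,
                                          drift_amplitude_mm = 0), seed = 1)
  expect_true(all(ph0$trajectory$resp_displacement == 0))

  expect_error(phantom_config(breath_period_s = -1), "positive")
  expect_true(all(diff(ph1$reflectors$depth_mm) > 0))
})

test_that("rendered image series has one frame per interval and moving masks", {
  ph <- make_breathing_phantom(phantom_config(duration_s = 10), seed = 3)
  ser <- render_image_series(ph, seq_params(), noise_sd = 0)
  expect_equal(dim(ser$frames)[3], floor(10 * 17.69))  # 176
  expect_equal(dim(ser$masks), dim(ser$frames))

  ## mask centroid moves by the programmed displacement / pixel size
  d <- approx(ph$trajectory$times, ph$trajectory$resp_displacement,
              xout = ser$timestamps)$y
  k_in <- which.max(d); k_ex <- which.min(d)
  centroid_row <- function(m) mean(which(m, arr.ind = TRUE)[, 1])
  shift_px <- centroid_row(ser$masks[, , k_in]) -
    centroid_row(ser$masks[, , k_ex])
  expect_equal(shift_px, (d[k_in] - d[k_ex]) / ser$pixel_size_mm,
               tolerance = 0.05)

  ## zero-motion phantom: all noiseless frames identical
  ph0 <- make_breathing_phantom(quiet_cfg(duration_s = 1,
                                          resp_amplitude_mm = 0,
                                          drift_amplitude_mm = 0), seed = 1)
  ser0 <- render_image_series(ph0, seq_params(), noise_sd = 0)
  expect_equal(max(abs(ser0$frames[, , 1] - ser0$frames[, , dim(ser0$frames)[3]])), 0)

  expect_error(render_image_series(ph, seq_params(), duration_s = 99),
               "exceeds")
})

test_that("ToF frames follow the surface with seeded invalid pixels", {
  ph <- make_breathing_phantom(phantom_config(duration_s = 30), seed = 4)
  cam <- tof_params(invalid_fraction = 0.2)
  tf <- simulate_tof_frames(ph, cam, seed = 4)
  expect_equal(dim(tf$frames)[3], 150)          # 30 s at 5 frames/s
  expect_equal(mean(tf$validity), 0.8, tolerance = 0.02)
  tf2 <- simulate_tof_frames(ph, cam, seed = 4)
  expect_identical(tf$frames, tf2$frames)

  ## flat static surface, no noise: constant frames
  ph0 <- make_breathing_phantom(quiet_cfg(duration_s = 2,
                                          resp_amplitude_mm = 0,
                                          drift_amplitude_mm = 0), seed = 1)
  tf0 <- simulate_tof_frames(ph0, tof_params(noise_sd_mm = 0,
                                             invalid_fraction = 0), seed = 1)
  expect_equal(max(abs(tf0$frames[, , 1] - tf0$frames[, , 10])), 0)

  expect_error(simulate_tof_frames(ph, tof_params(camera_height_mm = 100)),
               "camera height")
})

test_that("A-mode echoes land at round(2 z fs / c) for static reflectors", {
  for (depth in c(20, 50, 80)) {
    ph <- single_reflector_phantom(depth)
    am <- simulate_amode(ph, us_params(noise_sd = 0), seed = 1)
    rec <- reconstruct_amode(am)
    env <- Mod(rec$matrix[, 1])
    expected <- round(2 * depth / 1e3 * 20e6 / 1540)
    expect_lte(abs(which.max(env) - expected), 1)
  }
  ## zero reflectors -> all-zero series
  ph0 <- single_reflector_phantom()
  ph0$reflectors <- ph0$reflectors[0, ]
  ph0$scatterers <- ph0$scatterers[0, ]
  am0 <- simulate_amode(ph0, us_params(noise_sd = 0), seed = 1)
  expect_true(all(am0$rf == 0))
  ## too-deep reflector is a range error
  ph2 <- single_reflector_phantom(depth_mm = 200)
  expect_error(simulate_amode(ph2, us_params()), "deeper")
})

test_that("SDR stream is the amplitude-modulated tone at the configured rate", {
  expect_error(simulate_sdr_stream(function(t) 1, f_pt_hz = 2e6, fs_hz = 3e6,
                                   duration_s = 1), "alias")
  iq <- simulate_sdr_stream(function(t) 2, f_pt_hz = 3e6 / 32, fs_hz = 3e6,
                            duration_s = 0.5)
  expect_equal(length(iq$samples), 1.5e6)
  expect_equal(Mod(iq$samples), rep(2, 1.5e6), tolerance = 1e-12)
  ## single spectral line at f_pt (on-bin: 4096/32 = 128)
  spec <- Mod(fft(iq$samples[1:4096]))
  expect_equal(which.max(spec) - 1L, 128L)
  expect_lt(sort(spec, decreasing = TRUE)[2] / max(spec), 1e-9)
})
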