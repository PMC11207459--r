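test_that("SDR demodulation: block rate, pure-tone amplitude, linearity", {
  ## pure tone on an FFT bin: amplitude A -> A * block, CV < 1e-6
  f <- 3e6 / 512 * 100
  iq <- simulate_sdr_stream(function(t) rep(1.5, length(t)), f_pt_hz = f,
                            fs_hz = 3e6, duration_s = 0.1)
  pt <- demodulate_sdr(iq, block = 5120L)
  expect_equal(mean(pt$amplitude), 1.5 * 5120, tolerance = 1e-9)
  expect_lt(sd(pt$amplitude) / mean(pt$amplitude), 1e-6)
  ## block rate 3e6 / 5120 = 585.94 Hz
  expect_equal(1 / median(diff(pt$timestamps)), 585.9375, tolerance = 1e-9)
  ## trailing partial block dropped
  expect_equal(length(pt$amplitude), floor(0.1 * 3e6 / 5120))

  ## amplitude linearity: scaling the stream scales the series exactly
  iq2 <- iq; iq2$samples <- iq2$samples * 3
  expect_equal(demodulate_sdr(iq2, block = 5120L)$amplitude,
               3 * pt$amplitude, tolerance = 1e-12)

  ## median filter of order 9 leaves a constant series unchanged
  expect_equal(pt$amplitude, rep(pt$amplitude[1], length(pt$amplitude)),
               tolerance = 1e-6)
  expect_error(demodulate_sdr(iq, f_pt_hz = 2e6), "alias")
})

test_that("SDR round trip recovers the respiration curve", {
  ph <- make_breathing_phantom(phantom_config(duration_s = 20), seed = 31)
  resp <- ph$trajectory
  curve <- list(timestamps = resp$times, value = 3 + 0.05 * resp$resp_displacement)
  iq <- simulate_sdr_stream(curve, f_pt_hz = 20e3, fs_hz = 3e5,
                            noise_sd = 0.02, seed = 3)
  pt <- demodulate_sdr(iq, block = 512L)
  truth <- approx(curve$timestamps, curve$value, xout = pt$timestamps)$y
  expect_gt(cor(pt$amplitude, truth), 0.99)
})

test_that("band displacement converts integer profile shifts exactly", {
  ## synthetic series whose columns are the reference shifted by known lags
  set.seed(5)
  n <- 900
  base <- as.numeric(stats::filter(rnorm(n), rep(1, 25) / 25, circular = TRUE))
  base <- base - min(base) + 0.1
  shifts <- c(0, 3, -5, 12)
  m <- sapply(shifts, function(s) base[((seq_len(n) - 1 - s) %% n) + 1])
  am <- structure(list(matrix = m, fs_hz = 20e6, sound_speed_m_s = 1540,
                       pulse_freq_hz = 1e6,
                       timestamps = seq_along(shifts) - 1),
                  class = "amode_series")
  d <- ocm_band_displacement(am, c(0, 33), ref_column = 1, decimate = 1L,
                             max_lag = 30L)
  mm_per <- 1540 / (2 * 20e6) * 1e3
  expect_equal(d$value, shifts * mm_per, tolerance = 0.05 * mm_per)
  expect_equal(d$value[2], 0.1155, tolerance = 0.01)
  ## static series gives a zero curve
  m2 <- sapply(rep(0, 4), function(s) base)
  am2 <- am; am2$matrix <- m2
  expect_true(all(ocm_band_displacement(am2, c(0, 33), decimate = 1L)$value == 0))
})

test_that("anti-phase bands anticorrelate through the full OCM chain", {
  ph <- make_breathing_phantom(quiet_cfg(duration_s = 15), seed = 16)
  rec <- reconstruct_amode(simulate_amode(ph, us_params(prf_hz = 40), seed = 6))
  b1 <- ocm_band_displacement(rec, c(0, 33))
  b2 <- ocm_band_displacement(rec, c(33, 66))
  expect_lt(cor(b1$value, b2$value), -0.5)
  ## and band 1 tracks respiration with the configured coupling
  d <- approx(ph$trajectory$times, 0.3 * ph$trajectory$resp_displacement,
              xout = b1$timestamps)$y
  expect_gt(cor(b1$value, d), 0.9)
})

test_that("stream alignment interpolates onto a common grid and guards overlap", {
  t1 <- seq(0, 10, by = 0.05)
  f <- function(t) sin(2 * pi * t / 3)
  c1 <- displacement_curve(t1, f(t1))
  c2 <- displacement_curve(seq(0.5, 9.5, by = 0.03), f(seq(0.5, 9.5, by = 0.03)))
  b <- align_streams(list(a = c1, b = c2), rate_hz = 20)
  expect_lt(max(abs(b$curves[, "a"] - b$curves[, "b"])), 1e-3)
  expect_equal(b$timeline[1], 0.5)

  single <- align_streams(list(a = c1), rate_hz = 20)
  expect_equal(single$curves[, "a"], f(single$timeline), tolerance = 1e-3)

  c3 <- displacement_curve(t1 + 100, f(t1))
  expect_error(align_streams(list(a = c1, b = c3)), "overlap")
})

test_that("correlation matrix is symmetric with unit diagonal; constants are NA", {
  t1 <- seq(0, 10, by = 0.05)
  b <- align_streams(list(x = displacement_curve(t1, sin(t1)),
                          y = displacement_curve(t1, -sin(t1)),
                          z = displacement_curve(t1, rep(1, length(t1)))),
                     rate_hz = 10)
  r <- correlate_sensors(b)
  expect_equal(r$correlation, t(r$correlation))
  expect_equal(r$correlation["x", "x"], 1)
  expect_equal(r$correlation["x", "y"], -1, tolerance = 1e-12)
  expect_true(is.na(r$correlation["z", "z"]))
})

test_that("event detector recovers cough windows with few false alarms", {
  cfg <- phantom_config(duration_s = 60, deep_breath_times = 10,
                        cough_times = c(30.0, 30.9, 44.0))
  ph <- make_breathing_phantom(cfg, seed = 17)
  tr <- ph$trajectory
  ev <- detect_motion_events(tr$times, tr$resp_displacement)
  truth <- event_intervals(ph, "cough")
  hit <- vapply(seq_len(nrow(truth)), function(i)
    any(ev$start <= truth$end[i] & ev$end >= truth$start[i]), TRUE)
  expect_gte(mean(hit), 0.9)
  ## false events: windows not overlapping any cough or deep breath
  db <- event_intervals(ph, "deep_breath")
  allowed <- rbind(truth, db)
  false_ev <- vapply(seq_len(nrow(ev)), function(i)
    !any(allowed$start <= ev$end[i] + 0.5 & allowed$end >= ev$start[i] - 0.5),
    TRUE)
  expect_lte(sum(false_ev), 1)
})
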