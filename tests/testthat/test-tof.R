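test_that("waveform is the valid-pixel mean and is robust to invalid pixels", {
  ## constant 800 mm frames
  df <- structure(list(frames = array(800, c(8, 8, 5)),
                       validity = array(TRUE, c(8, 8, 5)),
                       timestamps = 0:4 / 5, frame_rate_hz = 5),
                  class = "depth_frames")
  expect_equal(extract_respiratory_waveform(df)$value, rep(800, 5))

  ## half the pixels invalid: unchanged
  df$validity[1:4, , ] <- FALSE
  expect_equal(extract_respiratory_waveform(df)$value, rep(800, 5))

  ## a frame with no valid pixel is interpolated and flagged
  df$frames[, , 3] <- 0
  df$validity[, , 3] <- FALSE
  wf <- extract_respiratory_waveform(df)
  expect_equal(wf$value[3], 800)
  expect_equal(attr(wf, "qc")$missing_frames, 3L)
})

test_that("waveform amplitude tracks the programmed surface motion linearly", {
  mk <- function(amp) {
    ph <- make_breathing_phantom(
      quiet_cfg(duration_s = 10, resp_amplitude_mm = amp,
                drift_amplitude_mm = 0, amp_jitter = 0, period_jitter = 0,
                surface_scale = 1),
      seed = 21)
    tf <- simulate_tof_frames(ph, tof_params(noise_sd_mm = 0,
                                             invalid_fraction = 0), seed = 1)
    extract_respiratory_waveform(tf)
  }
  w1 <- mk(4); w2 <- mk(8)
  ptp <- function(w) diff(range(w$value))
  expect_equal(ptp(w2) / ptp(w1), 2, tolerance = 1e-6)
  ## waveform amplitude within 5% of the programmed surface excursion
  expect_equal(ptp(w1), 4, tolerance = 0.05)

  ## waveform NRMSE vs truth degrades < 5% up to 50% invalid pixels
  ph2 <- make_breathing_phantom(phantom_config(duration_s = 20), seed = 22)
  ref <- extract_respiratory_waveform(
    simulate_tof_frames(ph2, tof_params(invalid_fraction = 0), seed = 5))
  half <- extract_respiratory_waveform(
    simulate_tof_frames(ph2, tof_params(invalid_fraction = 0.5), seed = 5))
  expect_lt(nrmse(half$value - mean(half$value),
                  ref$value - mean(ref$value)), 0.05)
})

test_that("ROI SNR matches hand computation and is scale invariant", {
  img <- matrix(0, 5, 5)
  img[1, 1:5] <- c(10, 10, 10, 10, 14)
  roi <- c(0, 1, 0, 5)    # first row, all 5 columns
  expect_equal(compute_roi_snr(img, roi), 10.8 / sd(c(10, 10, 10, 10, 14)),
               tolerance = 1e-12)
  expect_equal(compute_roi_snr(img, roi), 6.037, tolerance = 1e-3)
  expect_equal(compute_roi_snr(img * 3, roi), compute_roi_snr(img, roi))
  expect_error(compute_roi_snr(matrix(5, 4, 4), c(0, 2, 0, 2)), "zero")
  expect_error(compute_roi_snr(img, c(0, 9, 0, 2)), "roi")
})

test_that("SNR-map comparison implements the pooled two-sample t-test", {
  set.seed(31)
  a <- matrix(rnorm(40 * 40, mean = 10), 40, 40)
  roi <- c(8, 32, 8, 32)
  ## identical images: t = 0, p = 1
  rep0 <- compare_snr_maps(a, a, roi)
  expect_equal(rep0$t_statistic, 0)
  expect_equal(rep0$p_value, 1)
  expect_false(rep0$significant)

  ## a large added offset in the ROI is detected
  b <- a; b[9:32, 9:32] <- b[9:32, 9:32] + 50
  expect_true(compare_snr_maps(a, b, roi)$significant)

  expect_error(compare_snr_maps(a, a, c(0, 4, 0, 4), window = 5), "smaller")

  ## t statistic and p agree with the textbook pooled formula to 1e-10
  for (i in 1:10) {
    x <- rnorm(5 + i); y <- rnorm(7 + i, mean = 0.3)
    tt <- t.test(x, y, var.equal = TRUE)
    or <- t_test_oracle(x, y)
    expect_equal(unname(tt$statistic), or$t, tolerance = 1e-10)
    expect_equal(tt$p.value, or$p, tolerance = 1e-10)
  }
})

test_that("same-distribution SNR maps rarely differ significantly", {
  ## Monte-Carlo level check: two noise realizations, p > 0.05 mostly
  set.seed(77)
  n_sig <- 0
  for (i in 1:40) {
    a <- matrix(rnorm(30 * 30, mean = 12), 30, 30)
    b <- matrix(rnorm(30 * 30, mean = 12), 30, 30)
    r <- compare_snr_maps(a, b, c(5, 25, 5, 25))
    n_sig <- n_sig + r$significant
  }
  expect_lte(n_sig / 40, 0.1)
})
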