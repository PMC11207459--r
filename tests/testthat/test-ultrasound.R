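test_that("complex reconstruction recovers the echo envelope", {
  ## real cosine burst at the pulse frequency -> envelope peak at centre
  fs <- 20e6; f0 <- 1e6
  n <- 4000
  t <- (1:n) / fs
  tc <- 2000 / fs
  rf <- exp(-(t - tc)^2 / (2 * (1e-6)^2)) * cos(2 * pi * f0 * (t - tc))
  rec <- reconstruct_amode(matrix(rf, ncol = 1), fs_hz = fs,
                           pulse_freq_hz = f0)
  env <- Mod(rec$matrix[, 1])
  expect_lte(abs(which.max(env) - 2000), 2)
  expect_equal(max(env), 1, tolerance = 0.05)

  ## all-zero input stays zero
  rec0 <- reconstruct_amode(matrix(0, 100, 3), fs_hz = fs, pulse_freq_hz = f0)
  expect_true(all(Mod(rec0$matrix) == 0))
})

test_that("normalisation is max-1, scale-invariant, and guarded", {
  ph <- single_reflector_phantom(40)
  rec <- reconstruct_amode(simulate_amode(ph, us_params(noise_sd = 0.001),
                                          seed = 2))
  nm <- normalize_amode(rec)
  expect_equal(max(nm), 1)
  expect_gte(min(nm), 0)
  rec7 <- rec; rec7$matrix <- rec7$matrix * 7
  expect_equal(normalize_amode(rec7), nm, tolerance = 1e-12)
  rec0 <- rec; rec0$matrix <- rec0$matrix * 0
  expect_error(normalize_amode(rec0), "all-zero")
})

test_that("depth bands hold exactly floor(2 z fs / c) rows", {
  ph <- single_reflector_phantom(40)
  rec <- reconstruct_amode(simulate_amode(ph, us_params(noise_sd = 0), seed = 1))
  d <- amode_depth_mm(rec)
  expect_equal(sum(d >= 0 & d < 33), floor(2 * 0.033 * 20e6 / 1540))
  nm <- normalize_amode(rec)
  ## constant matrix -> constant band median; outlier row does not move it
  cm <- nm; cm[] <- 0.5
  attr(cm, "timestamps") <- attr(nm, "timestamps")
  attr(cm, "depth_mm") <- attr(nm, "depth_mm")
  bm <- band_median(cm, c(0, 33))
  expect_true(all(bm$value == 0.5))
  cm[3, ] <- 50
  expect_true(all(band_median(cm, c(0, 33))$value == 0.5))
  expect_error(band_median(cm, c(200, 300)), "empty")
})

test_that("Otsu + 3D components give near-unbiased areas on random ellipses", {
  set.seed(9)
  px <- 2.34
  for (i in 1:20) {
    a <- runif(1, 10, 25); b <- runif(1, 8, 20)
    img <- matrix(0.2, 96, 96)
    r2 <- ((row(img) - 48.5) / b)^2 + ((col(img) - 48.5) / a)^2
    img[r2 <= 1] <- 0.9
    ## lone stack of 3 identical frames
    st <- array(img, c(96, 96, 3))
    area <- segment_bladder_area(st, pixel_size_mm = px)
    expect_equal(area$value[2], pi * a * b * px^2, tolerance = 0.02)
  }
})

test_that("bladder area tracking follows contractions and ignores small blobs", {
  cfg <- phantom_config(region = "pelvis", duration_s = 10)
  ph <- make_breathing_phantom(cfg, seed = 13)
  ser <- render_image_series(ph, seq_params(), noise_sd = 0)
  area <- segment_bladder_area(ser)
  truth <- approx(ph$trajectory$times, ph$trajectory$bladder_area,
                  xout = area$timestamps)$y
  expect_lt(max(abs(area$value - truth) / truth), 0.03)

  ## contraction halves ... dips the area curve exactly when labelled
  con <- approx(ph$trajectory$times, ph$trajectory$contraction,
                xout = area$timestamps)$y
  expect_lt(min(area$value[con > 0.9]) / median(area$value[con == 0]), 0.75)

  ## two bright blobs: only the larger (bladder) contributes
  img <- ser$frames[, , 1]
  img[2:4, 2:4] <- 0.95
  st <- array(img, c(dim(img), 2))
  a2 <- segment_bladder_area(st, ser$pixel_size_mm)
  base <- segment_bladder_area(array(ser$frames[, , 1], c(dim(img), 2)),
                               ser$pixel_size_mm)
  expect_equal(a2$value, base$value)
})

test_that("band medians respond to motion in both depth bands", {
  cfg <- quiet_cfg(duration_s = 12)
  ph <- make_breathing_phantom(cfg, seed = 14)
  rec <- reconstruct_amode(simulate_amode(ph, us_params(prf_hz = 40), seed = 3))
  b1 <- band_median(rec, c(0, 33))
  b2 <- band_median(rec, c(33, 66))
  ## both medians carry respiratory power well above their noise floor
  for (b in list(b1, b2)) {
    sp <- Mod(fft(b$value - mean(b$value)))^2
    n <- length(b$value)
    resp_band <- which((seq_len(n) - 1) / (n / 40) > 0.15 &
                         (seq_len(n) - 1) / (n / 40) < 0.6)
    expect_gt(sum(sp[resp_band]) / sum(sp[2:(n %/% 2)]), 0.2)
  }
})
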