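## one moderate radial acquisition shared by the tone tests
ph_pt <- make_breathing_phantom(phantom_config(duration_s = 2), seed = 12)
ks_pt <- simulate_radial_kspace(ph_pt, seq_params_radial(n_spokes = 256))
resp_pt <- list(timestamps = ph_pt$trajectory$times,
                value = ph_pt$trajectory$resp_displacement)

test_that("tone injection is guarded against spectral overlap and aliasing", {
  expect_error(inject_pilot_tone(ks_pt, resp_pt, pt_offset_hz = 0),
               "spectral overlap")
  expect_error(inject_pilot_tone(ks_pt, resp_pt, pt_offset_hz = 30e3),
               "spectral overlap")
  expect_error(inject_pilot_tone(ks_pt, resp_pt, pt_offset_hz = 70e3),
               "alias")
})

test_that("tone with gain 0 only touches the PT bin, and extraction is exact", {
  ## on-bin offset: 48 kHz at fs 128 kHz over 256 samples -> bin 96
  ks_tone <- inject_pilot_tone(ks_pt, resp_pt, gain = 0, noise_sd = 0)
  diff_spec <- Mod(mvfft(ks_tone$lines - ks_pt$lines))
  hot <- which(diff_spec > 1e-6 * max(diff_spec), arr.ind = TRUE)
  expect_true(all(hot[, 1] == hot[1, 1]))   # a single readout-frequency bin

  ## constant amplitude on signal-free k-space: CV below 1e-6
  ks0 <- ks_pt; ks0$lines <- ks0$lines * 0
  pt0 <- extract_pt_signal(inject_pilot_tone(ks0, resp_pt, gain = 0,
                                             noise_sd = 0))
  expect_lt(sd(pt0$amplitude) / mean(pt0$amplitude), 1e-6)

  ## clean k-space has no detectable tone
  expect_error(extract_pt_signal(ks_pt), "tone not detected")
})

test_that("extracted amplitude tracks the injected displacement curve", {
  ks_mod <- inject_pilot_tone(ks_pt, resp_pt, gain = 0.5, noise_sd = 0)
  pt <- extract_pt_signal(ks_mod)
  d <- approx(resp_pt$timestamps, resp_pt$value, xout = pt$timestamps)$y
  expect_gt(cor(pt$amplitude, d), 0.999)

  ## invariant to a global k-space phase
  ks_rot <- ks_mod; ks_rot$lines <- ks_rot$lines * exp(1i * 1.1)
  expect_equal(extract_pt_signal(ks_rot)$amplitude, pt$amplitude,
               tolerance = 1e-12)

  ## multi-channel input reduces to the strongest channel
  weak <- ks_mod$lines * 0.05
  ks3 <- ks_mod
  ks3$lines <- array(c(weak, ks_mod$lines), c(dim(ks_mod$lines), 2))
  expect_equal(extract_pt_signal(ks3)$amplitude, pt$amplitude,
               tolerance = 1e-12)
})

test_that("mask post-processing fills holes, keeps one component, idempotent", {
  m <- matrix(FALSE, 40, 40)
  m[10:30, 10:30] <- TRUE
  m[20, 20] <- FALSE              # 1-pixel hole
  m[35, 35] <- TRUE               # stray island (area 1 vs ~441)
  out <- postprocess_mask(m)
  expect_true(out[20, 20])
  expect_false(out[35, 35])
  expect_identical(postprocess_mask(out), out)
  expect_lte(max(EBImage::bwlabel(out)), 1)

  z <- postprocess_mask(matrix(FALSE, 5, 5))
  expect_true(attr(z, "empty_mask"))
  expect_true(all(!z))
})

test_that("boundary displacement is the median top row times pixel size", {
  ## translated mask: 3 rows at 2.34 mm -> 7.02 mm
  base <- matrix(FALSE, 30, 30); base[10:20, 5:25] <- TRUE
  shifted <- matrix(FALSE, 30, 30); shifted[13:23, 5:25] <- TRUE
  curve <- extract_boundary_displacement(
    array(c(base, shifted, base), c(30, 30, 3)), pixel_size_mm = 2.34)
  expect_equal(curve$value, c(0, 7.02, 0))

  ## median of mixed top rows {10,10,12,14,14} -> 12
  m <- matrix(FALSE, 30, 5)
  tops <- c(10, 10, 12, 14, 14)
  for (j in 1:5) m[tops[j]:25, j] <- TRUE
  c2 <- extract_boundary_displacement(array(c(m, m), c(30, 5, 2)), 1)
  expect_equal(c2$value, c(0, 0))  # static
  ## absolute median row check via a one-frame comparison against row 10
  ref <- matrix(FALSE, 30, 5); ref[10:25, ] <- TRUE
  c3 <- extract_boundary_displacement(array(c(ref, m), c(30, 5, 2)), 1)
  expect_equal(c3$value[2] - c3$value[1], 12 - 10)

  ## empty frames are interpolated and QC-counted
  c4 <- extract_boundary_displacement(
    array(c(base, matrix(FALSE, 30, 30), base), c(30, 30, 3)), 1)
  expect_equal(attr(c4, "qc")$n_missing, 1)
  expect_equal(length(c4$value), 3)
})

test_that("gating keeps exactly the lines allowed by the rule", {
  lines <- matrix(1 + 0i, 16, 100)
  ks <- new_kspace_series(lines, angles = seq(0, 3, length.out = 100),
                          timestamps = seq(0, 9.9, by = 0.1),
                          seq = seq_params_radial(n_spokes = 100))
  ## displacement exceeding 20 mm on exactly 10% of line timestamps
  d <- rep(5, 100); d[41:50] <- 25
  disp <- displacement_curve(seq(0, 9.9, by = 0.1), d)
  g <- gate_kspace(ks, disp, threshold_mm = 20)
  expect_equal(attr(g, "retained_fraction"), 0.9)
  expect_equal(ncol(g$lines), 90)

  ## threshold Inf is the identity
  g_inf <- gate_kspace(ks, disp, threshold_mm = Inf)
  expect_identical(g_inf$lines, ks$lines)
  expect_equal(attr(g_inf, "retained_fraction"), 1)

  ## event rule removes exactly the labelled windows
  ev <- data.frame(start = 2.0, end = 2.5)
  ge <- gate_kspace(ks, events = ev)
  expect_equal(sum(!attr(ge, "retained")),
               sum(ks$timestamps >= 2.0 & ks$timestamps <= 2.5))

  expect_error(gate_kspace(ks, disp, threshold_mm = -1), "every")
})
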