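test_that("spoke timestamps and golden-angle ordering are exact", {
  ph <- make_breathing_phantom(quiet_cfg(duration_s = 1), seed = 1)
  sq <- seq_params_radial(n_spokes = 20)
  ks <- simulate_radial_kspace(ph, sq)
  expect_equal(ks$timestamps, (0:19) * 3.57e-3)
  expect_equal(diff(ks$angles), rep(pi * (3 - sqrt(5)), 19), tolerance = 1e-12)
})

test_that("the DC sample of any spoke equals the image integral", {
  ph <- make_breathing_phantom(quiet_cfg(duration_s = 1), seed = 2)
  img <- matrix(0, 128, 128)
  ## uniform disc
  r2 <- (row(img) - 64.5)^2 + (col(img) - 64.5)^2
  img[r2 <= 30^2] <- 1
  rho <- mrmotion:::spoke_radii(256, 128)
  s <- mrmotion:::ndft_spoke(img, rho, theta = 0.7, N = 128)
  expect_equal(Re(s[rho == 0]), sum(img), tolerance = 1e-10)
  expect_equal(Im(s[rho == 0]), 0, tolerance = 1e-8)
})

test_that("static-phantom adjoint reconstruction matches the rendered image", {
  ph <- make_breathing_phantom(quiet_cfg(duration_s = 2, resp_amplitude_mm = 0,
                                         drift_amplitude_mm = 0), seed = 1)
  img <- phantom_image(ph, 0)
  ks <- simulate_radial_kspace(ph, seq_params_radial(n_spokes = 402))
  rec <- reconstruct_nufft(ks)
  expect_lt(nrmse(rec, img), 0.05)
  ## deterministic
  expect_identical(rec, reconstruct_nufft(ks))
  ## all-zero k-space reconstructs to zero
  ks0 <- ks; ks0$lines <- ks0$lines * 0
  expect_true(all(reconstruct_nufft(ks0) == 0))
})
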