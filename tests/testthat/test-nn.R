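test_that("U-Net forward and gradients match a double-precision oracle", {
  set.seed(4)
  xs <- array(runif(32 * 32 * 1 * 2), c(32, 32, 1, 2))
  gs <- array(as.numeric(rbinom(32 * 32 * 2, 1, 0.3)), c(32, 32, 1, 2))
  ps <- mrmotion:::with_seed(2, mrmotion:::unet_init(2L))
  res <- mrmotion:::cpp_unet_train_step(xs, gs, ps, 1)
  expect_equal(res$loss, unet_loss_ref(ps, xs, gs), tolerance = 1e-5)

  ## analytic gradient vs numeric directional derivative of the oracle
  dir <- lapply(ps, function(p)
    list(W = array(rnorm(length(p$W)), dim(p$W)), b = rnorm(length(p$b))))
  gdotv <- sum(mapply(function(g, v) sum(g$dW * v$W) + sum(g$db * v$b),
                      res$grads[names(ps)], dir))
  eps <- 1e-6
  shift <- function(s) {
    p2 <- ps
    for (nm in names(ps)) {
      p2[[nm]]$W <- ps[[nm]]$W + s * dir[[nm]]$W
      p2[[nm]]$b <- ps[[nm]]$b + s * dir[[nm]]$b
    }
    unet_loss_ref(p2, xs, gs)
  }
  num <- (shift(eps) - shift(-eps)) / (2 * eps)
  expect_equal(gdotv, num, tolerance = 1e-4)
})

test_that("conv kernels agree with finite differences", {
  set.seed(1)
  x <- array(rnorm(12 * 10 * 2 * 2), c(12, 10, 2, 2))
  p <- mrmotion:::with_seed(1, mrmotion:::init_conv(3, 3, 2, 3))
  dy <- array(rnorm(12 * 10 * 3 * 2), c(12, 10, 3, 2))
  b <- mrmotion:::nn_conv_bwd(x, p, dy)
  f <- function(xx, pp) sum(mrmotion:::nn_conv(xx, pp) * dy)
  eps <- 1e-3
  for (i in sample(length(p$W), 4)) {
    p2 <- p; p2$W[i] <- p2$W[i] + eps
    p3 <- p; p3$W[i] <- p3$W[i] - eps
    expect_equal(b$dw[i], (f(x, p2) - f(x, p3)) / (2 * eps), tolerance = 2e-2)
  }
})

test_that("the C++ 1D CNN step matches the layer-wise R reference", {
  set.seed(2)
  L <- 96L; N <- 7L
  p <- mrmotion:::with_seed(1, mrmotion:::cnn1d_init(L, c(4L, 8L), 9L,
                                                     hidden = 16L))
  X <- matrix(rnorm(L * N), L, N)
  y <- rnorm(N)
  fwd <- mrmotion:::cnn1d_forward(p, array(X, c(L, 1, 1, N)))
  res <- mrmotion:::cpp_cnn1d_run(X, y, p, 1, TRUE)
  pred <- mrmotion:::cpp_cnn1d_run(X, y, p, 1, FALSE)$pred
  expect_equal(fwd$out[, 1], pred, tolerance = 1e-5)
  l <- mrmotion:::huber_loss(fwd$out, matrix(y, ncol = 1), delta = 1)
  expect_equal(l$loss, res$loss, tolerance = 1e-6)
  g <- mrmotion:::cnn1d_backward(p, fwd, l$grad)
  for (nm in names(p))
    expect_equal(as.numeric(g[[nm]]$dW), as.numeric(res$grads[[nm]]$dW),
                 tolerance = 1e-4)
})

test_that("segmenter training is seed-deterministic and validates inputs", {
  ph <- make_breathing_phantom(phantom_config(duration_s = 4), seed = 6)
  ser <- render_image_series(ph, seq_params())
  hy <- unet_hyper(epochs = 2, base_width = 2L)
  m1 <- train_liver_segmenter(ser$frames, ser$masks, hyper = hy, seed = 7)
  m2 <- train_liver_segmenter(ser$frames, ser$masks, hyper = hy, seed = 7)
  expect_identical(m1$loss_curve, m2$loss_curve)
  expect_identical(m1$params, m2$params)

  expect_error(train_liver_segmenter(ser$frames[, , 1:20],
                                     ser$masks[, , 1:20], hyper = hy),
               "at least 50")
  empty <- ser$masks; empty[] <- FALSE
  expect_error(train_liver_segmenter(ser$frames, empty, hyper = hy),
               "empty masks")
})

test_that("motion model learns a linear PT-displacement map and normalisation is invariant", {
  ## clean sinusoid-like breathing, affine PT
  t <- seq(0, 60, by = 1 / 17.69)
  d <- 5 * sin(2 * pi * t / 4)^4 + 2
  ptv <- 3 + 0.4 * d
  pt <- pt_series(t, ptv)
  disp <- displacement_curve(t, d)
  mm <- train_motion_model(pt, disp, hyper = fcn_hyper(epochs = 150), seed = 1)
  expect_lt(mm$test_mse_norm, 1e-3)

  pred <- predict_displacement(mm, pt)
  fit <- coef(lm(pred$value ~ d))
  expect_equal(unname(fit[2]), 1, tolerance = 0.01)   # gain within 1%
  expect_equal(unname(fit[1]), 0, tolerance = 0.05 * diff(range(d)))

  ## constant displacement is learned exactly (MSE ~ 0)
  disp_c <- displacement_curve(t, rep(3, length(t)))
  mc <- train_motion_model(pt, disp_c, hyper = fcn_hyper(epochs = 100), seed = 1)
  expect_lt(mc$test_mse_norm, 1e-4)

  ## affine input with updated stats gives identical output
  mm2 <- mm
  alpha <- 2.5; beta <- -1
  mm2$stats$pt_mean <- alpha * mm$stats$pt_mean + beta
  mm2$stats$pt_sd <- alpha * mm$stats$pt_sd
  mm2$stats$pt_range <- alpha * mm$stats$pt_range + beta
  pt2 <- pt_series(t, alpha * ptv + beta)
  expect_equal(predict_displacement(mm2, pt2)$value, pred$value,
               tolerance = 1e-10)

  ## sinusoidal PT input predicts at the same dominant frequency
  ts2 <- seq(0, 30, by = 1 / 17.69)
  pt_sin <- pt_series(ts2, mean(ptv) + sd(ptv) * sin(2 * pi * ts2 / 4))
  out <- predict_displacement(mm, pt_sin)
  peak_freq <- function(x, dt) {
    sp <- Mod(fft(x - mean(x)))
    n <- length(x)
    which.max(sp[2:(n %/% 2)]) / (n * dt)
  }
  df <- 17.69 / length(ts2)
  expect_lt(abs(peak_freq(out$value, 1 / 17.69) -
                peak_freq(pt_sin$amplitude, 1 / 17.69)), 1.5 * df)

  ## non-overlapping time ranges fail alignment
  expect_error(train_motion_model(pt_series(t + 1000, ptv), disp),
               "overlap")
})
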