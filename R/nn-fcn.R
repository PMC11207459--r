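## Fully connected Pilot-Tone -> displacement motion model:
## 5 hidden layers of 100 units with ReLU, linear output head,
## MSE loss, Adam lr 1e-3. Input is a sliding window of normalised
## PT samples; output is displacement on a min-max normalised scale.

mlp_forward <- function(params, x) {
  acts <- list(x)
  n_layers <- length(params)
  h <- x
  for (i in seq_len(n_layers - 1L)) {
    h <- nn_relu(nn_dense(h, params[[i]]))
    acts[[i + 1L]] <- h
  }
  list(acts = acts, out = nn_dense(h, params[[n_layers]]))
}

mlp_backward <- function(params, fwd, dout) {
  n_layers <- length(params)
  g <- vector("list", n_layers)
  names(g) <- names(params)
  b <- nn_dense_bwd(fwd$acts[[n_layers]], params[[n_layers]], dout)
  g[[n_layers]] <- list(dW = b$dW, db = b$db)
  dh <- b$dx
  for (i in rev(seq_len(n_layers - 1L))) {
    dh <- nn_relu_bwd(fwd$acts[[i + 1L]], dh)
    b <- nn_dense_bwd(fwd$acts[[i]], params[[i]], dh)
    g[[i]] <- list(dW = b$dW, db = b$db)
    dh <- b$dx
  }
  g
}

#' Average the Pilot-Tone amplitude within each image frame interval
#'
#' The PT is sampled once per k-space line, much faster than the image
#' frame rate; for calibration each frame gets the mean amplitude of the
#' lines acquired during its interval (frames without lines are
#' interpolated).
#'
#' @param pt a [pt_series()].
#' @param frame_times frame timestamps (s).
#' @return numeric vector, one amplitude per frame.
#' @export
align_pt_to_frames <- function(pt, frame_times) {
  if (max(pt$timestamps) < min(frame_times) ||
      min(pt$timestamps) > max(frame_times))
    stop("PT and frame time ranges do not overlap", call. = FALSE)
  edges <- c(frame_times, 2 * frame_times[length(frame_times)] -
               frame_times[length(frame_times) - 1])
  bin <- findInterval(pt$timestamps, edges)
  keep <- bin >= 1 & bin <= length(frame_times)
  agg <- tapply(pt$amplitude[keep], bin[keep], mean)
  out <- rep(NA_real_, length(frame_times))
  out[as.integer(names(agg))] <- agg
  if (anyNA(out)) {
    ok <- !is.na(out)
    out <- approx(frame_times[ok], out[ok], xout = frame_times, rule = 2)$y
  }
  out
}

#' Motion-model hyperparameters
#'
#' @param epochs training epochs.
#' @param lr Adam learning rate (1e-3 per the training recipe).
#' @param batch_size minibatch size.
#' @param window sliding-window length (PT samples per input).
#' @param hidden hidden layer widths.
#' @return named list.
#' @export
fcn_hyper <- function(epochs = 300L, lr = 1e-3, batch_size = 32L,
                      window = 16L, hidden = rep(100L, 5L))
  list(epochs = as.integer(epochs), lr = lr,
       batch_size = as.integer(batch_size), window = as.integer(window),
       hidden = as.integer(hidden))

#' Train the Pilot-Tone motion model
#'
#' Maps a sliding window of normalised Pilot-Tone amplitudes to liver
#' superior-inferior displacement with a fully connected network (five
#' hidden layers of 100 ReLU units), trained with MSE loss and Adam at
#' learning rate 0.001 on a contiguous 70-20-10 split. Displacement is
#' min-max normalised to [0, 1] for training; the held-out test MSE on
#' that scale and the corresponding RMSE in mm are stored on the model.
#'
#' @param pt a [pt_series()], already aligned to `disp` timestamps
#'   (same length) or sampled faster (it is then frame-averaged with
#'   [align_pt_to_frames()]).
#' @param disp a [displacement_curve()] in mm.
#' @param hyper a [fcn_hyper()] list.
#' @param seed training seed.
#' @return object of class `motion_model` with normalisation stats,
#'   weights, loss curve and test metrics (`test_mse_norm`,
#'   `test_rmse_mm`).
#' @export
train_motion_model <- function(pt, disp, hyper = fcn_hyper(), seed = 0L) {
  if (max(pt$timestamps) < min(disp$timestamps) ||
      min(pt$timestamps) > max(disp$timestamps))
    stop("PT and displacement time ranges do not overlap", call. = FALSE)
  x_raw <- if (length(pt$amplitude) == length(disp$value)) pt$amplitude
           else align_pt_to_frames(pt, disp$timestamps)
  y_raw <- disp$value
  W <- hyper$window
  n <- length(y_raw)
  if (n <= W + 10) stop("too few aligned samples", call. = FALSE)

  idx_all <- W:n
  split <- contiguous_split(length(idx_all))
  tr_ids <- idx_all[split$train]

  pt_mean <- mean(x_raw[tr_ids]); pt_sd <- sd(x_raw[tr_ids])
  if (pt_sd == 0) pt_sd <- 1
  d_min <- min(y_raw[tr_ids]); d_max <- max(y_raw[tr_ids])
  d_rng <- if (d_max > d_min) d_max - d_min else 1
  xn <- (x_raw - pt_mean) / pt_sd
  yn <- (y_raw - d_min) / d_rng

  make_x <- function(ids)
    t(vapply(ids, function(i) xn[(i - W + 1L):i], numeric(W)))
  X <- list(train = make_x(idx_all[split$train]),
            test = make_x(idx_all[split$test]),
            val = make_x(idx_all[split$val]))
  Y <- list(train = yn[idx_all[split$train]],
            test = yn[idx_all[split$test]],
            val = yn[idx_all[split$val]])

  with_seed(seed, {
    widths <- c(W, hyper$hidden, 1L)
    params <- lapply(seq_len(length(widths) - 1L),
                     function(i) init_dense(widths[i], widths[i + 1L]))
    names(params) <- paste0("fc", seq_along(params))
    state <- adam_init(params)
    step <- 0L
    loss_curve <- numeric(hyper$epochs)
    n_tr <- nrow(X$train)
    for (ep in seq_len(hyper$epochs)) {
      ep_loss <- 0
      for (b in epoch_batches(n_tr, hyper$batch_size)) {
        fwd <- mlp_forward(params, X$train[b, , drop = FALSE])
        l <- mse_loss(fwd$out, matrix(Y$train[b], ncol = 1))
        g <- mlp_backward(params, fwd, l$grad)
        step <- step + 1L
        upd <- adam_step(params, g, state, step, hyper$lr)
        params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + l$loss * length(b)
      }
      loss_curve[ep] <- ep_loss / n_tr
    }
    pred_test <- mlp_forward(params, X$test)$out
    test_mse <- mean((pred_test - Y$test)^2)
    structure(list(params = params, hyper = hyper,
                   stats = list(pt_mean = pt_mean, pt_sd = pt_sd,
                                pt_range = range(x_raw[tr_ids]),
                                disp_min = d_min, disp_range = d_rng),
                   split_idx = lapply(split, function(s) idx_all[s]),
                   loss_curve = loss_curve,
                   test_mse_norm = test_mse,
                   test_rmse_mm = sqrt(test_mse) * d_rng,
                   seed = as.integer(seed)),
              class = "motion_model")
  })
}

#' @export
print.motion_model <- function(x, ...) {
  cat(sprintf("<motion_model> window %d, test MSE (normalised) %.4g, RMSE %.2f mm\n",
              x$hyper$window, x$test_mse_norm, x$test_rmse_mm))
  invisible(x)
}

#' Predict displacement from a Pilot-Tone series
#'
#' Applies the trained motion model at every PT timestamp (the input is
#' left-padded with its first sample so early timestamps have a full
#' window) and de-normalises to mm with the stored statistics. Inputs
#' far outside the training amplitude range trigger an extrapolation
#' warning.
#'
#' @param model a `motion_model`.
#' @param pt a [pt_series()].
#' @return a [displacement_curve()] in mm.
#' @export
predict_displacement <- function(model, pt) {
  st <- model$stats
  W <- model$hyper$window
  xn <- (pt$amplitude - st$pt_mean) / st$pt_sd
  half <- diff(st$pt_range) / 2
  centre <- mean(st$pt_range)
  if (half > 0 && any(abs(pt$amplitude - centre) > 5 * half))
    warning("PT amplitudes outside 5x the training range; extrapolating")
  xp <- c(rep(xn[1], W - 1L), xn)
  Xw <- t(vapply(seq_along(xn), function(i) xp[i:(i + W - 1L)], numeric(W)))
  yn <- mlp_forward(model$params, Xw)$out[, 1]
  displacement_curve(pt$timestamps, yn * st$disp_range + st$disp_min,
                     reference = "end-exhale minimum")
}
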