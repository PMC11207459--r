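## 1D CNN mapping a normalised A-mode depth profile to bladder area.
## Trunk: 4 conv blocks (kernel 9, stride 2, channels 8-16-32-64, ReLU);
## head: flatten + hidden dense layer, with a direct linear skip path
## from the raw input profile to the output. The flatten head keeps the
## depth-position information a pooled head would discard, and the skip
## path lets the network contain a plain linear readout of the profile,
## which the conv features then correct. Trained with AdamW (lr 1e-4,
## weight decay 5e-4), Huber loss, early stopping on a validation
## split. 1D signals are laid out as (L, 1, C, N) and share the 2D conv
## kernels with stride (2,1) and padding (4,0).

cnn1d_stride <- c(2L, 1L)
cnn1d_pad <- c(4L, 0L)

cnn1d_init <- function(n_input, channels = c(8L, 16L, 32L, 64L), kernel = 9L,
                       hidden = 64L) {
  params <- list()
  cin <- 1L
  len <- n_input
  for (i in seq_along(channels)) {
    params[[paste0("c", i)]] <- init_conv(kernel, 1L, cin, channels[i])
    cin <- channels[i]
    len <- (len + 2L * 4L - kernel) %/% 2L + 1L
  }
  params$fc <- init_dense(len * cin, hidden)
  params$head <- init_dense(hidden + n_input, 1L)
  attr(params, "flat_dim") <- len * cin
  params
}

cnn1d_forward <- function(params, x) {
  n_conv <- length(params) - 2L
  acts <- list(x)
  h <- x
  for (i in seq_len(n_conv)) {
    h <- nn_relu(nn_conv(h, params[[paste0("c", i)]],
                         stride = cnn1d_stride, pad = cnn1d_pad))
    acts[[i + 1L]] <- h
  }
  d <- dim(h)
  flat <- t(matrix(h, nrow = prod(d[1:3]), ncol = d[4]))
  hid <- nn_relu(nn_dense(flat, params$fc))
  xin <- t(matrix(x, nrow = dim(x)[1], ncol = dim(x)[4]))
  hx <- cbind(hid, xin)
  list(acts = acts, flat = flat, hid = hid, hx = hx,
       out = nn_dense(hx, params$head), conv_dim = d)
}

cnn1d_backward <- function(params, fwd, dout) {
  n_conv <- length(params) - 2L
  g <- list()
  bh <- nn_dense_bwd(fwd$hx, params$head, dout)
  g$head <- list(dW = bh$dW, db = bh$db)
  dhid <- nn_relu_bwd(fwd$hid, bh$dx[, seq_len(ncol(fwd$hid)), drop = FALSE])
  bf <- nn_dense_bwd(fwd$flat, params$fc, dhid)
  g$fc <- list(dW = bf$dW, db = bf$db)
  dh <- array(t(bf$dx), fwd$conv_dim)
  for (i in rev(seq_len(n_conv))) {
    nm <- paste0("c", i)
    dh <- nn_relu_bwd(fwd$acts[[i + 1L]], dh)
    b <- nn_conv_bwd(fwd$acts[[i]], params[[nm]], dh,
                     stride = cnn1d_stride, pad = cnn1d_pad)
    g[[nm]] <- list(dW = b$dw, db = b$db)
    dh <- b$dx
  }
  g
}

#' Area-predictor hyperparameters
#'
#' Defaults follow the stated recipe: AdamW with learning rate 1e-4 and
#' weight decay 5e-4, Huber loss, early stopping on validation loss.
#'
#' @param epochs maximum epochs.
#' @param lr AdamW learning rate.
#' @param weight_decay decoupled weight decay.
#' @param batch_size minibatch size.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param n_input depth-profile length fed to the network (profiles are
#'   linearly resampled to this length).
#' @param channels conv channels per block.
#' @param kernel conv kernel length.
#' @param huber_delta Huber transition point (normalised area units).
#' @param input_scale multiplier applied to the normalised input
#'   features; larger inputs shrink the weight magnitudes the linear
#'   readout needs, which shortens the distance Adam must travel at a
#'   fixed learning rate.
#' @return named list.
#' @export
cnn_hyper <- function(epochs = 700L, lr = 1e-4, weight_decay = 5e-4,
                      batch_size = 64L, patience = 80L, n_input = 384L,
                      channels = c(8L, 16L, 32L, 64L), kernel = 9L,
                      huber_delta = 1, input_scale = 1)
  list(epochs = as.integer(epochs), lr = lr, weight_decay = weight_decay,
       batch_size = as.integer(batch_size), patience = as.integer(patience),
       n_input = as.integer(n_input), channels = as.integer(channels),
       kernel = as.integer(kernel), huber_delta = huber_delta,
       input_scale = input_scale)

## resample normalised profiles to the network input length; x is a
## (depth x time) matrix
profiles_to_input <- function(profiles, n_input) {
  n_d <- nrow(profiles)
  grid <- seq(1, n_d, length.out = n_input)
  apply(profiles, 2, function(col) approx(seq_len(n_d), col, xout = grid)$y)
}

## nearest-timestamp pairing of ultrasound columns to area samples
pair_columns_to_area <- function(col_ts, area) {
  vapply(col_ts, function(t) area$value[which.min(abs(area$timestamps - t))], 0)
}

#' Train the 1D CNN bladder-area predictor
#'
#' Maps a single normalised A-mode depth profile to the mid-sagittal
#' bladder area (mm^2). Ultrasound columns are paired to area samples by
#' nearest timestamp; profiles are resampled to a fixed input length;
#' the target area is z-normalised with training statistics. Training
#' uses AdamW (lr 1e-4, weight decay 5e-4), the Huber loss, and early
#' stopping on a contiguous validation split; the held-out test MAE in
#' mm^2 is stored on the model.
#'
#' @param amode an `amode_series` (or list of them, one per subject).
#' @param area a matching [displacement_curve()] in mm^2 (or list).
#' @param hyper a [cnn_hyper()] list.
#' @param seed training seed.
#' @return object of class `area_model` with weights, stats,
#'   `test_mae_mm2` (frame-level: predictions averaged within each image
#'   frame before comparison, since the ground truth exists once per
#'   frame) and `test_mae_column_mm2` (per ultrasound column).
#' @export
train_area_predictor <- function(amode, area, hyper = cnn_hyper(),
                                 seed = 0L) {
  if (inherits(amode, "amode_series")) amode <- list(amode)
  if (inherits(area, "displacement_curve")) area <- list(area)
  stopifnot(length(amode) == length(area))
  xs <- list(); ys <- list(); subj <- integer(0); frame_key <- character(0)
  for (s in seq_along(amode)) {
    norm <- normalize_amode(amode[[s]])
    xs[[s]] <- profiles_to_input(norm, hyper$n_input)
    ts_col <- attr(norm, "timestamps")
    ys[[s]] <- pair_columns_to_area(ts_col, area[[s]])
    nearest <- vapply(ts_col, function(t)
      which.min(abs(area[[s]]$timestamps - t)), 0L)
    frame_key <- c(frame_key, paste(s, nearest))
    subj <- c(subj, rep(s, ncol(xs[[s]])))
  }
  X <- do.call(cbind, xs)          # n_input x N
  y <- unlist(ys)
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("non-finite training inputs", call. = FALSE)
  if (length(y) < 100) stop("need at least 100 paired samples", call. = FALSE)
  split <- contiguous_split(length(y), subjects = subj)

  y_mean <- mean(y[split$train]); y_sd <- sd(y[split$train])
  if (y_sd == 0) y_sd <- 1
  yn <- (y - y_mean) / y_sd

  ## input normalisation: centre each depth bin, scale by one global
  ## standard deviation. Centring + O(1) scaling keeps the weight scale
  ## Adam must reach at the stated learning rate attainable, while a
  ## single global scale (unlike per-bin scaling) does not blow
  ## noise-only bins up to full amplitude
  x_mean <- rowMeans(X[, split$train, drop = FALSE])
  x_sd <- max(sd(X[, split$train, drop = FALSE] - x_mean), 1e-3) /
    hyper$input_scale
  X <- (X - x_mean) / x_sd

  as_batch <- function(ids) X[, ids, drop = FALSE]

  val_huber <- function(params, val_x, val_y, delta) {
    pred <- cpp_cnn1d_run(val_x, numeric(ncol(val_x)), params, delta,
                          FALSE)$pred
    huber_loss(matrix(pred, ncol = 1), matrix(val_y, ncol = 1),
               delta = delta)$loss
  }

  with_seed(seed, {
    params <- cnn1d_init(hyper$n_input, hyper$channels, hyper$kernel)
    state <- adam_init(params)
    step <- 0L
    best <- list(loss = Inf, params = params, epoch = 0L)
    val_x <- as_batch(split$val); val_y <- yn[split$val]
    n_tr <- length(split$train)
    loss_curve <- numeric(0)
    ## tail weight averaging (Polyak): running mean of the last epochs'
    ## weights removes the optimiser's jitter around the optimum
    avg <- NULL; n_avg <- 0L
    for (ep in seq_len(hyper$epochs)) {
      ep_loss <- 0
      for (b in epoch_batches(n_tr, hyper$batch_size)) {
        ids <- split$train[b]
        res <- cpp_cnn1d_run(as_batch(ids), yn[ids], params,
                             hyper$huber_delta, TRUE)
        step <- step + 1L
        upd <- adam_step(params, res$grads, state, step, hyper$lr,
                         weight_decay = hyper$weight_decay)
        ## AdamW decay must not touch the bias-free structure attribute
        attr(upd$params, "flat_dim") <- attr(params, "flat_dim")
        params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + res$loss * length(ids)
      }
      loss_curve <- c(loss_curve, ep_loss / n_tr)
      ## validation loss smoothed over the trailing epochs: the raw
      ## per-epoch loss on a small split is too noisy for stable early
      ## stopping and model selection
      val_hist <- c(if (exists("val_hist", inherits = FALSE)) val_hist,
                    val_huber(params, val_x, val_y, hyper$huber_delta))
      vl <- mean(tail(val_hist, 5))
      if (vl < best$loss - 1e-7)
        best <- list(loss = vl, params = params, epoch = ep)
      if (ep > hyper$epochs %/% 3) {
        if (is.null(avg)) {
          avg <- params; n_avg <- 1L
        } else {
          for (nm in names(params)) {
            avg[[nm]]$W <- avg[[nm]]$W + (params[[nm]]$W - avg[[nm]]$W) / (n_avg + 1L)
            avg[[nm]]$b <- avg[[nm]]$b + (params[[nm]]$b - avg[[nm]]$b) / (n_avg + 1L)
          }
          n_avg <- n_avg + 1L
        }
      }
      if (ep - best$epoch >= hyper$patience) break
    }
    ## model selection on the validation split: best single epoch vs
    ## the tail average
    params <- best$params
    if (!is.null(avg)) {
      attr(avg, "flat_dim") <- attr(params, "flat_dim")
      if (val_huber(avg, val_x, val_y, hyper$huber_delta) < best$loss)
        params <- avg
    }
    test_pred <- cpp_cnn1d_run(as_batch(split$test),
                               numeric(length(split$test)), params,
                               hyper$huber_delta, FALSE)$pred * y_sd + y_mean
    mae_col <- mean(abs(test_pred - y[split$test]))
    ## the ground truth exists once per image frame; columns inside a
    ## frame are replicate measurements, so the primary metric averages
    ## predictions within each frame before comparing
    fp <- tapply(test_pred, frame_key[split$test], mean)
    fy <- tapply(y[split$test], frame_key[split$test], mean)
    mae <- mean(abs(fp - fy))
    structure(list(params = params, hyper = hyper,
                   stats = list(area_mean = y_mean, area_sd = y_sd,
                                x_mean = x_mean, x_sd = x_sd),
                   split_idx = split, loss_curve = loss_curve,
                   stopped_epoch = best$epoch,
                   test_mae_mm2 = mae, test_mae_column_mm2 = mae_col,
                   seed = as.integer(seed)),
              class = "area_model")
  })
}

#' @export
print.area_model <- function(x, ...) {
  cat(sprintf("<area_model> stopped at epoch %d, test MAE %.1f mm^2\n",
              x$stopped_epoch, x$test_mae_mm2))
  invisible(x)
}

#' Predict bladder area from A-mode data
#'
#' @param model an `area_model`.
#' @param amode an `amode_series` (resampled to the training depth grid
#'   length internally).
#' @return a [displacement_curve()] in mm^2, clamped at 0; the number of
#'   clamped samples is attached as attribute `n_clamped`.
#' @export
predict_area <- function(model, amode) {
  norm <- normalize_amode(amode)
  X <- profiles_to_input(norm, model$hyper$n_input)
  X <- (X - model$stats$x_mean) / model$stats$x_sd
  yn <- cpp_cnn1d_run(X, numeric(ncol(X)), model$params,
                      model$hyper$huber_delta, FALSE)$pred
  area <- yn * model$stats$area_sd + model$stats$area_mean
  n_clamped <- sum(area < 0)
  area <- pmax(area, 0)
  ts <- attr(norm, "timestamps")
  if (is.null(ts)) ts <- seq_len(ncol(X)) - 1
  out <- displacement_curve(ts, area, reference = "predicted area",
                            units = "mm^2")
  attr(out, "n_clamped") <- n_clamped
  out
}
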