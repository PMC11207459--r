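## A small 2D U-Net (3 resolution levels, configurable base width,
## nearest-neighbour upsampling, single-conv decoder blocks, sigmoid
## output). The whole-network forward/backward runs in C++ (src/unet.cpp);
## weight init and the Adam loop stay in R.

unet_init <- function(base = 4L, in_ch = 1L) {
  F1 <- base; F2 <- 2L * base; F4 <- 4L * base
  list(
    e1c1 = init_conv(3, 3, in_ch, F1), e1c2 = init_conv(3, 3, F1, F1),
    e2c1 = init_conv(3, 3, F1, F2),    e2c2 = init_conv(3, 3, F2, F2),
    bc1  = init_conv(3, 3, F2, F4),    bc2  = init_conv(3, 3, F4, F4),
    d2   = init_conv(3, 3, F4 + F2, F2),
    d1   = init_conv(3, 3, F2 + F1, F1),
    out  = init_conv(1, 1, F1, 1L)
  )
}

#' U-Net training hyperparameters
#'
#' Defaults follow the stated segmentation training recipe: Dice loss,
#' Adam with learning rate 1e-4, batch size 10, 30 epochs. `base_width`
#' sets the number of filters at the first resolution level (doubling
#' per level over 3 levels); 4 is the smallest width that segments the
#' synthetic anatomy reliably within a single-CPU budget.
#'
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param base_width filters at the first level.
#' @param threshold probability threshold for binary masks.
#' @return named list.
#' @export
unet_hyper <- function(epochs = 30L, lr = 1e-4, batch_size = 10L,
                       base_width = 4L, threshold = 0.5)
  list(epochs = as.integer(epochs), lr = lr,
       batch_size = as.integer(batch_size),
       base_width = as.integer(base_width), threshold = threshold)

#' Train the 2D U-Net liver segmenter
#'
#' Trains a small U-Net to segment the liver (the bright organ under the
#' lung interface) on fast calibration frames, using Dice loss, Adam
#' (lr 1e-4) and batch size 10 with a 70-20-10 train-test-validation
#' split. The split is contiguous in time within each subject to avoid
#' leakage between temporally adjacent frames.
#'
#' @param frames numeric array (H x W x T) of magnitude images.
#' @param masks logical array (H x W x T) of ground-truth masks.
#' @param subjects optional integer vector (length T) of subject ids;
#'   the split is stratified within subject.
#' @param split fractions (train, test, val) summing to 1.
#' @param hyper a [unet_hyper()] list.
#' @param seed training seed (weight init + batch order).
#' @param verbose print per-epoch loss.
#' @return object of class `unet_model`: parameters, normalisation
#'   stats, split indices, per-epoch loss curve.
#' @export
train_liver_segmenter <- function(frames, masks, subjects = NULL,
                                  split = c(train = 0.7, test = 0.2, val = 0.1),
                                  hyper = unet_hyper(), seed = 0L,
                                  verbose = FALSE) {
  stopifnot(length(dim(frames)) == 3L, all(dim(frames) == dim(masks)))
  n <- dim(frames)[3]
  if (n < 50) stop("need at least 50 frames to train", call. = FALSE)
  idx <- contiguous_split(n, split, subjects)
  empty_frac <- mean(vapply(idx$train, function(k) sum(masks[, , k]) == 0, TRUE))
  if (empty_frac > 0.1)
    stop("more than 10% of training frames have empty masks", call. = FALSE)
  scale <- max(frames)
  H <- dim(frames)[1]; W <- dim(frames)[2]

  with_seed(seed, {
    params <- unet_init(hyper$base_width)
    state <- adam_init(params)
    step <- 0L
    loss_curve <- numeric(hyper$epochs)
    for (ep in seq_len(hyper$epochs)) {
      ep_loss <- 0
      batches <- epoch_batches(length(idx$train), hyper$batch_size)
      for (b in batches) {
        ids <- idx$train[b]
        x <- array(frames[, , ids] / scale, c(H, W, 1L, length(ids)))
        gtruth <- array(as.numeric(masks[, , ids]), c(H, W, 1L, length(ids)))
        res <- cpp_unet_train_step(x, gtruth, params, 1)
        step <- step + 1L
        upd <- adam_step(params, res$grads, state, step, hyper$lr)
        params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + res$loss * length(ids)
      }
      loss_curve[ep] <- ep_loss / length(idx$train)
      if (verbose)
        message(sprintf("epoch %d/%d dice-loss %.4f", ep, hyper$epochs,
                        loss_curve[ep]))
    }
    structure(list(params = params, hyper = hyper, scale = scale,
                   split_idx = idx, loss_curve = loss_curve,
                   seed = as.integer(seed)),
              class = "unet_model")
  })
}

#' Predict segmentation masks with a trained U-Net
#'
#' @param model a `unet_model`.
#' @param frames numeric array (H x W x T).
#' @param postprocess apply [postprocess_mask()] to each frame.
#' @param chunk frames per forward pass (memory control).
#' @return logical array (H x W x T).
#' @export
predict_liver_masks <- function(model, frames, postprocess = TRUE,
                                chunk = 16L) {
  if (length(dim(frames)) == 2L) frames <- array(frames, c(dim(frames), 1L))
  H <- dim(frames)[1]; W <- dim(frames)[2]; n <- dim(frames)[3]
  out <- array(FALSE, c(H, W, n))
  for (start in seq(1L, n, by = chunk)) {
    ids <- start:min(start + chunk - 1L, n)
    x <- array(frames[, , ids] / model$scale, c(H, W, 1L, length(ids)))
    prob <- cpp_unet_infer(x, model$params)
    for (j in seq_along(ids)) {
      m <- prob[, , 1L, j] >= model$hyper$threshold
      if (postprocess) m <- postprocess_mask(m)
      out[, , ids[j]] <- m
    }
  }
  out
}

#' Dice score of a segmenter on a frame subset
#'
#' @param model a `unet_model`.
#' @param frames,masks full arrays the model's split refers to.
#' @param which split name (`"test"`, `"val"`, `"train"`) or an integer
#'   index vector.
#' @param postprocess apply mask post-processing before scoring.
#' @return mean Dice over the selected frames.
#' @export
evaluate_segmenter <- function(model, frames, masks, which = "test",
                               postprocess = TRUE) {
  ids <- if (is.character(which)) model$split_idx[[which]] else which
  pred <- predict_liver_masks(model, frames[, , ids, drop = FALSE],
                              postprocess = postprocess)
  mean(vapply(seq_along(ids), function(j)
    dice_coef(pred[, , j], masks[, , ids[j]]), 0))
}
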