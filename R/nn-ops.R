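## Minimal explicit-backprop neural-network primitives.
## Activations are R arrays dim (H, W, C, N); conv kernels run in C++
## (im2col + single-precision BLAS gemm). Dense layers stay in base R.
## All parameter updates are Adam/AdamW; everything is seeded and
## deterministic on one BLAS thread.

nn_conv <- function(x, p, stride = c(1L, 1L), pad = c(1L, 1L))
  cpp_conv2d_fwd(x, p$W, p$b, as.integer(stride), as.integer(pad))

nn_conv_bwd <- function(x, p, dy, stride = c(1L, 1L), pad = c(1L, 1L))
  cpp_conv2d_bwd(x, p$W, dy, as.integer(stride), as.integer(pad))

nn_relu <- function(x) { x[x < 0] <- 0; x }
nn_relu_bwd <- function(y, dy) { dy[y <= 0] <- 0; dy }

nn_sigmoid <- function(x) 1 / (1 + exp(-x))

## He-normal initialisation (fan-in), uses the current RNG stream
init_conv <- function(kh, kw, cin, cout) {
  W <- array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
             c(kh, kw, cin, cout))
  list(W = W, b = numeric(cout))
}

init_dense <- function(n_in, n_out) {
  list(W = matrix(rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = numeric(n_out))
}

nn_dense <- function(x, p) sweep(x %*% p$W, 2, p$b, "+")
nn_dense_bwd <- function(x, p, dy)
  list(dx = dy %*% t(p$W), dW = crossprod(x, dy), db = colSums(dy))

## ---- optimiser -----------------------------------------------------------

adam_init <- function(params)
  lapply(params, function(p) list(mW = p$W * 0, vW = p$W * 0,
                                  mb = p$b * 0, vb = p$b * 0))

## AdamW when weight_decay > 0 (decoupled decay, applied to W only)
adam_step <- function(params, grads, state, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (nm in names(params)) {
    s <- state[[nm]]
    g <- grads[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    upd <- lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    if (weight_decay > 0) upd <- upd + lr * weight_decay * params[[nm]]$W
    params[[nm]]$W <- params[[nm]]$W - upd
    params[[nm]]$b <- params[[nm]]$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

## ---- losses --------------------------------------------------------------

## soft Dice loss over a batch of sigmoid probabilities
dice_loss <- function(p, g, smooth = 1) {
  num <- 2 * sum(p * g) + smooth
  den <- sum(p) + sum(g) + smooth
  grad <- -(2 * g * den - num) / den^2
  list(loss = 1 - num / den, grad = grad)
}

mse_loss <- function(pred, target) {
  r <- pred - target
  list(loss = mean(r^2), grad = 2 * r / length(r))
}

huber_loss <- function(pred, target, delta = 1) {
  r <- pred - target
  a <- abs(r)
  quad <- a <= delta
  loss <- mean(ifelse(quad, 0.5 * r^2, delta * (a - 0.5 * delta)))
  grad <- ifelse(quad, r, delta * sign(r)) / length(r)
  list(loss = loss, grad = grad)
}

## deterministic minibatch index order for one epoch
epoch_batches <- function(n, batch_size) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

## contiguous-in-time train/test/val split, optionally per subject
contiguous_split <- function(n, split = c(train = 0.7, test = 0.2, val = 0.1),
                             subjects = NULL) {
  if (abs(sum(split) - 1) > 1e-8)
    stop("split fractions must sum to 1", call. = FALSE)
  if (is.null(subjects)) subjects <- rep(1L, n)
  out <- list(train = integer(0), test = integer(0), val = integer(0))
  for (s in unique(subjects)) {
    idx <- which(subjects == s)
    m <- length(idx)
    n_tr <- round(split[[1]] * m)
    n_te <- round(split[[2]] * m)
    out$train <- c(out$train, idx[seq_len(n_tr)])
    out$test <- c(out$test, idx[n_tr + seq_len(min(n_te, m - n_tr))])
    if (m > n_tr + n_te) out$val <- c(out$val, idx[(n_tr + n_te + 1):m])
  }
  out
}
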