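# double-precision reference U-Net forward (same topology)
conv2d_ref <- function(x, W, b, pad = 1) {
  # x: (H,Wd,C,N), W: (kh,kw,C,Co)
  d <- dim(x); H <- d[1]; Wd <- d[2]; C <- d[3]; N <- d[4]
  kh <- dim(W)[1]; kw <- dim(W)[2]; Co <- dim(W)[4]
  Ho <- H + 2*pad - kh + 1; Wo <- Wd + 2*pad - kw + 1
  xp <- array(0, c(H + 2*pad, Wd + 2*pad, C, N))
  xp[pad + 1:H, pad + 1:Wd, , ] <- x
  y <- array(0, c(Ho, Wo, Co, N))
  for (n in 1:N) for (o in 1:Co) {
    acc <- matrix(b[o], Ho, Wo)
    for (c in 1:C) for (i in 1:kh) for (j in 1:kw)
      acc <- acc + W[i, j, c, o] * xp[(i):(i+Ho-1), (j):(j+Wo-1), c, n]
    y[, , o, n] <- acc
  }
  y
}
relu_ref <- function(x) pmax(x, 0)
pool_ref <- function(x) {
  d <- dim(x); H <- d[1]; Wd <- d[2]
  a <- x[seq(1, H, 2), seq(1, Wd, 2), , , drop = FALSE]
  b <- x[seq(2, H, 2), seq(1, Wd, 2), , , drop = FALSE]
  c <- x[seq(1, H, 2), seq(2, Wd, 2), , , drop = FALSE]
  e <- x[seq(2, H, 2), seq(2, Wd, 2), , , drop = FALSE]
  pmax(pmax(a, b), pmax(c, e))
}
up_ref <- function(x) {
  d <- dim(x)
  y <- array(0, c(2*d[1], 2*d[2], d[3], d[4]))
  for (i in 0:1) for (j in 0:1)
    y[seq(1+i, 2*d[1], 2), seq(1+j, 2*d[2], 2), , ] <- x
  y
}
cat_ref <- function(a, b) {
  d <- dim(a); db <- dim(b)
  y <- array(0, c(d[1], d[2], d[3] + db[3], d[4]))
  y[, , 1:d[3], ] <- a; y[, , d[3] + 1:db[3], ] <- b
  y
}
unet_loss_ref <- function(p, x, g, smooth = 1) {
  e1 <- relu_ref(conv2d_ref(x, p$e1c1$W, p$e1c1$b))
  e1b <- relu_ref(conv2d_ref(e1, p$e1c2$W, p$e1c2$b))
  p1 <- pool_ref(e1b)
  e2 <- relu_ref(conv2d_ref(p1, p$e2c1$W, p$e2c1$b))
  e2b <- relu_ref(conv2d_ref(e2, p$e2c2$W, p$e2c2$b))
  p2 <- pool_ref(e2b)
  b1 <- relu_ref(conv2d_ref(p2, p$bc1$W, p$bc1$b))
  b2 <- relu_ref(conv2d_ref(b1, p$bc2$W, p$bc2$b))
  c2 <- cat_ref(up_ref(b2), e2b)
  d2 <- relu_ref(conv2d_ref(c2, p$d2$W, p$d2$b))
  c1 <- cat_ref(up_ref(d2), e1b)
  d1 <- relu_ref(conv2d_ref(c1, p$d1$W, p$d1$b))
  logit <- conv2d_ref(d1, p$out$W, p$out$b, pad = 0)
  prob <- 1/(1 + exp(-logit))
  num <- 2*sum(prob*g) + smooth
  den <- sum(prob) + sum(g) + smooth
  1 - num/den
}
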