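#' Extract a respiratory waveform from depth frames
#'
#' For each frame the Z component is averaged over all valid pixels
#' (invalid/overexposed pixels are ignored frame by frame). Frames with
#' no valid pixel are marked missing, linearly interpolated, and listed
#' in the `qc` attribute.
#'
#' @param series a `depth_frames` object.
#' @return a [displacement_curve()] in mm (mean camera-to-surface
#'   distance per frame).
#' @export
extract_respiratory_waveform <- function(series) {
  stopifnot(inherits(series, "depth_frames"))
  n_t <- dim(series$frames)[3]
  z <- vapply(seq_len(n_t), function(k) {
    v <- series$validity[, , k]
    if (!any(v)) return(NA_real_)
    mean(series$frames[, , k][v])
  }, 0)
  missing <- which(is.na(z))
  if (length(missing) == n_t)
    stop("no frame has a valid pixel", call. = FALSE)
  if (length(missing) > 0) {
    ok <- !is.na(z)
    z <- approx(series$timestamps[ok], z[ok], xout = series$timestamps,
                rule = 2)$y
  }
  out <- displacement_curve(series$timestamps, z,
                            reference = "camera distance")
  attr(out, "qc") <- list(missing_frames = missing)
  out
}

check_roi <- function(roi, dims) {
  ## roi: c(row0, row1, col0, col1), 0-based, half-open
  if (length(roi) != 4 || any(roi < 0) || roi[2] > dims[1] || roi[4] > dims[2]
      || roi[2] <= roi[1] || roi[4] <= roi[3])
    stop("roi must be c(row0, row1, col0, col1), 0-based half-open, inside the image",
         call. = FALSE)
  list(rows = (roi[1] + 1):roi[2], cols = (roi[3] + 1):roi[4])
}

#' Region-of-interest SNR of a magnitude image
#'
#' Mean divided by sample standard deviation of the pixel values in a
#' rectangular ROI; scale invariant.
#'
#' @param image numeric matrix.
#' @param roi `c(row0, row1, col0, col1)`, 0-based, half-open.
#' @return scalar SNR.
#' @export
compute_roi_snr <- function(image, roi) {
  r <- check_roi(roi, dim(image))
  vals <- image[r$rows, r$cols]
  if (length(vals) < 2) stop("roi must contain at least 2 pixels", call. = FALSE)
  s <- sd(vals)
  if (s == 0) stop("zero standard deviation in roi", call. = FALSE)
  mean(vals) / s
}

## pixelwise SNR map from sliding-window mean/sd (window must fit; the
## map is only defined where the full window lies inside the image)
snr_map <- function(image, window = 5L) {
  H <- nrow(image); W <- ncol(image)
  if (window %% 2 != 1) stop("window must be odd", call. = FALSE)
  h <- (window - 1L) %/% 2L
  box <- function(M) {
    ## zero-padded 2D integral image
    P <- rbind(0, cbind(0, t(apply(apply(M, 2, cumsum), 1, cumsum))))
    out <- matrix(NA_real_, H, W)
    ih <- (h + 1):(H - h); jh <- (h + 1):(W - h)
    out[ih, jh] <- P[ih + h + 1, jh + h + 1] - P[ih - h, jh + h + 1] -
      P[ih + h + 1, jh - h] + P[ih - h, jh - h]
    out
  }
  n <- window^2
  mu <- box(image) / n
  varn <- pmax((box(image^2) - n * mu^2) / (n - 1), 0)
  mu / sqrt(varn)
}

#' Compare pixelwise SNR maps of two images inside an ROI
#'
#' Builds sliding-window (default 5x5) pixelwise SNR maps of both
#' images, then runs a two-sided independent two-sample t-test (pooled
#' variance) on the two ROI populations. Because sliding windows overlap,
#' neighbouring map pixels are strongly correlated; the test populations
#' are therefore subsampled on a window-stride grid inside the ROI so
#' the independence assumption of the t-test holds.
#'
#' @param img_a,img_b congruent numeric matrices.
#' @param roi `c(row0, row1, col0, col1)`, 0-based half-open; must be at
#'   least as large as the window.
#' @param alpha significance threshold.
#' @param window sliding-window size (odd).
#' @param var_equal pooled-variance (Student) test when `TRUE`, Welch
#'   otherwise.
#' @return an `snr_report`: ROI, per-image SNR mean +/- sd,
#'   `t_statistic`, `p_value`, `significant`.
#' @export
compare_snr_maps <- function(img_a, img_b, roi, alpha = 0.05, window = 5L,
                             var_equal = TRUE) {
  stopifnot(all(dim(img_a) == dim(img_b)))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  r <- check_roi(roi, dim(img_a))
  if (length(r$rows) < window || length(r$cols) < window)
    stop("roi smaller than the SNR window", call. = FALSE)
  sub_r <- r$rows[seq(1, length(r$rows), by = window)]
  sub_c <- r$cols[seq(1, length(r$cols), by = window)]
  ma <- snr_map(img_a, window)[sub_r, sub_c]
  mb <- snr_map(img_b, window)[sub_r, sub_c]
  a <- ma[is.finite(ma)]; b <- mb[is.finite(mb)]
  tt <- t.test(a, b, var.equal = var_equal)
  structure(list(roi = roi,
                 snr_a = c(mean = mean(a), sd = sd(a)),
                 snr_b = c(mean = mean(b), sd = sd(b)),
                 t_statistic = unname(tt$statistic),
                 p_value = tt$p.value, alpha = alpha,
                 significant = tt$p.value < alpha),
            class = "snr_report")
}

#' @export
print.snr_report <- function(x, ...) {
  cat(sprintf("<snr_report> SNR %.2f+/-%.2f vs %.2f+/-%.2f; t = %.2f, p = %.3f (%ssignificant at alpha = %.2f)\n",
              x$snr_a["mean"], x$snr_a["sd"], x$snr_b["mean"], x$snr_b["sd"],
              x$t_statistic, x$p_value,
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}
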