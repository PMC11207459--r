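#' Depth-band displacement from A-mode data by cross-correlation
#'
#' For every time column, the integer depth shift of the band's
#' magnitude profile against a reference column is found by maximising
#' the normalised cross-correlation over a lag window, then refined to
#' sub-sample precision by parabolic interpolation around the peak.
#' Shifts are converted to mm via `c/(2 fs)`; positive displacement
#' means the interfaces move away from the transducer (deeper).
#'
#' @param amode an `amode_series`.
#' @param depth_band_mm band interval (mm), e.g. `c(0, 33)` or
#'   `c(33, 66)`.
#' @param ref_column reference column index.
#' @param max_lag maximum shift searched (decimated samples).
#' @param min_peak minimum correlation at the peak; columns below it are
#'   flagged low-confidence in the `qc` attribute.
#' @param decimate depth-axis decimation factor before correlation (the
#'   echo envelope is much wider than one RF sample, so this loses no
#'   information while keeping the lag search cheap).
#' @return a [displacement_curve()] in mm with attribute `qc`
#'   (`low_confidence` indices).
#' @export
ocm_band_displacement <- function(amode, depth_band_mm, ref_column = 1L,
                                  max_lag = 80L, min_peak = 0.2,
                                  decimate = 4L) {
  norm <- normalize_amode(amode)
  depth <- attr(norm, "depth_mm")
  rows <- which(depth >= depth_band_mm[1] & depth < depth_band_mm[2])
  if (length(rows) == 0) stop("empty depth band", call. = FALSE)
  if (ref_column < 1 || ref_column > ncol(norm))
    stop("invalid reference column", call. = FALSE)
  rows <- rows[seq(1L, length(rows), by = decimate)]
  B <- norm[rows, , drop = FALSE]
  n_r <- nrow(B); n_c <- ncol(B)
  lags <- -max_lag:max_lag
  core <- (max_lag + 1):(n_r - max_lag)   # rows valid at every lag
  if (length(core) < 8)
    stop("band too narrow for the configured max_lag", call. = FALSE)
  ref <- B[, ref_column]
  cc <- matrix(0, length(lags), n_c)
  for (i in seq_along(lags)) {
    ## profile shifted down by `lag` matches ref[core - lag]
    r <- ref[core - lags[i]]
    cc[i, ] <- suppressWarnings(cor(B[core, , drop = FALSE], r))
  }
  cc[!is.finite(cc)] <- -1
  best <- apply(cc, 2, which.max)
  peak <- cc[cbind(best, seq_len(n_c))]
  shift <- lags[best]
  ## parabolic sub-sample refinement (skipped for exact matches, where
  ## the asymmetry of the correlation curve would bias a perfect peak)
  interior <- best > 1 & best < length(lags) & peak < 1 - 1e-9
  if (any(interior)) {
    i0 <- best[interior]; j0 <- which(interior)
    y0 <- cc[cbind(i0, j0)]
    ym <- cc[cbind(i0 - 1L, j0)]
    yp <- cc[cbind(i0 + 1L, j0)]
    den <- ym - 2 * y0 + yp
    delta <- ifelse(abs(den) > 1e-12, 0.5 * (ym - yp) / den, 0)
    shift[interior] <- shift[interior] + pmax(pmin(delta, 0.5), -0.5)
  }
  mm_per_sample <- amode$sound_speed_m_s / (2 * amode$fs_hz) * 1e3 * decimate
  out <- displacement_curve(amode$timestamps, shift * mm_per_sample,
                            reference = "reference column")
  attr(out, "qc") <- list(low_confidence = which(peak < min_peak))
  out
}

#' Align sensor curves onto a common uniform timeline
#'
#' Linearly interpolates each named curve onto a uniform grid at `rate`
#' over the overlapping time support of all curves.
#'
#' @param curves named list of [pt_series()] / [displacement_curve()]
#'   objects (or lists with `timestamps` and `value`/`amplitude`).
#' @param rate_hz grid rate (Hz).
#' @param normalize z-normalise each curve on the grid.
#' @return a `sensor_bundle`: `timeline` (s) and `curves` (matrix, one
#'   column per sensor).
#' @export
align_streams <- function(curves, rate_hz = 20, normalize = FALSE) {
  stopifnot(is.list(curves), length(curves) >= 1, !is.null(names(curves)))
  get_tv <- function(cv) {
    v <- if (!is.null(cv$value)) cv$value else cv$amplitude
    list(t = cv$timestamps, v = v)
  }
  tv <- lapply(curves, get_tv)
  t0 <- max(vapply(tv, function(x) min(x$t), 0))
  t1 <- min(vapply(tv, function(x) max(x$t), 0))
  if (t1 <= t0) stop("curves have no overlapping time support", call. = FALSE)
  grid <- seq(t0, t1, by = 1 / rate_hz)
  m <- vapply(tv, function(x) approx(x$t, x$v, xout = grid)$y,
              numeric(length(grid)))
  m <- matrix(m, ncol = length(curves),
              dimnames = list(NULL, names(curves)))
  if (normalize)
    m <- apply(m, 2, function(col) {
      s <- sd(col)
      if (s == 0) col - mean(col) else (col - mean(col)) / s
    })
  structure(list(timeline = grid, curves = m, rate_hz = rate_hz),
            class = "sensor_bundle")
}

#' Detect aberrant-motion events on a curve
#'
#' Flags samples whose amplitude or first derivative is a robust
#' (median/MAD) outlier, and merges flagged samples into event windows.
#' Intended for deep breaths and coughs on respiratory traces.
#'
#' @param timestamps,value the curve.
#' @param z_threshold robust z-score threshold.
#' @param merge_gap_s flagged samples closer than this are merged into
#'   one window.
#' @return data.frame with `start`, `end` (s).
#' @export
detect_motion_events <- function(timestamps, value, z_threshold = 4,
                                 merge_gap_s = 0.6) {
  dt <- median(diff(timestamps))
  deriv <- c(0, diff(value)) / dt
  rz <- function(x) {
    m <- median(x); s <- median(abs(x - m)) * 1.4826
    if (s == 0) return(rep(0, length(x)))
    (x - m) / s
  }
  flag <- abs(rz(deriv)) > z_threshold | rz(value) > z_threshold
  if (!any(flag)) return(data.frame(start = numeric(0), end = numeric(0)))
  ft <- timestamps[flag]
  breaks <- which(diff(ft) > merge_gap_s)
  starts <- ft[c(1, breaks + 1)]
  ends <- ft[c(breaks, length(ft))]
  data.frame(start = starts, end = ends)
}

#' Cross-sensor correlation and event report
#'
#' Pearson correlation matrix over the aligned window plus per-sensor
#' aberrant-motion event windows. Constant curves have undefined
#' correlations, reported as `NA`.
#'
#' @param bundle a [align_streams()] result.
#' @return list with `correlation` (matrix) and `events` (named list of
#'   data.frames from [detect_motion_events()]).
#' @export
correlate_sensors <- function(bundle) {
  stopifnot(inherits(bundle, "sensor_bundle"))
  m <- bundle$curves
  cm <- suppressWarnings(cor(m))
  diag(cm) <- ifelse(apply(m, 2, sd) == 0, NA_real_, 1)
  events <- lapply(colnames(m), function(nm)
    detect_motion_events(bundle$timeline, m[, nm]))
  names(events) <- colnames(m)
  list(correlation = cm, events = events)
}
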