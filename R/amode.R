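#' Depth axis of an A-mode series
#'
#' Sample `i` corresponds to depth `i * c / (2 fs)` (round-trip time).
#'
#' @param series an `amode_series`.
#' @return depths in mm, one per row.
#' @export
amode_depth_mm <- function(series)
  seq_len(amode_nrow(series)) * series$sound_speed_m_s / (2 * series$fs_hz) * 1e3

amode_nrow <- function(series)
  if (!is.null(series$matrix)) nrow(series$matrix) else nrow(series$rf)

#' Reconstruct complex A-mode data from raw RF echoes
#'
#' Quadrature demodulation at the pulse centre frequency followed by a
#' low-pass filter yields one complex analytic sample per depth, so the
#' magnitude is the echo envelope. The depth axis is a surrogate for
#' distance through the body; the time axis spans the acquisition.
#'
#' @param raw an `amode_series` with an `$rf` matrix (or a plain real
#'   matrix plus `fs_hz`/`pulse_freq_hz` arguments).
#' @param fs_hz,pulse_freq_hz,sound_speed_m_s overrides when `raw` is a
#'   bare matrix.
#' @return the `amode_series` with `$matrix` set to the complex
#'   depth x time signal.
#' @export
reconstruct_amode <- function(raw, fs_hz = NULL, pulse_freq_hz = NULL,
                              sound_speed_m_s = 1540) {
  if (is.matrix(raw)) {
    if (is.null(fs_hz) || is.null(pulse_freq_hz))
      stop("bare matrices need fs_hz and pulse_freq_hz", call. = FALSE)
    raw <- structure(list(rf = raw, matrix = NULL, fs_hz = fs_hz,
                          pulse_freq_hz = pulse_freq_hz,
                          sound_speed_m_s = sound_speed_m_s,
                          timestamps = seq_len(ncol(raw)) - 1),
                     class = "amode_series")
  }
  rf <- raw$rf
  if (is.null(rf)) stop("no raw RF data to reconstruct", call. = FALSE)
  if (!is.matrix(rf)) stop("raw echoes must form a matrix", call. = FALSE)
  n <- nrow(rf)
  t_axis <- seq_len(n) / raw$fs_hz
  carrier <- exp(-2i * pi * raw$pulse_freq_hz * t_axis)
  bf <- signal::butter(4, 0.8 * raw$pulse_freq_hz / (raw$fs_hz / 2),
                       type = "low")
  demod <- rf * carrier   # column-wise via recycling along rows
  re <- apply(Re(demod), 2, function(col) signal::filtfilt(bf, col))
  im <- apply(Im(demod), 2, function(col) signal::filtfilt(bf, col))
  out <- raw
  out$matrix <- matrix(complex(real = re, imaginary = im), n, ncol(rf)) * 2
  out
}

#' Normalise an A-mode magnitude matrix
#'
#' The magnitude of the complex signal is divided by its maximum, so all
#' values lie in [0, 1] with the maximum exactly 1 (scale invariant).
#'
#' @param series an `amode_series` with `$matrix`, or a numeric/complex
#'   matrix.
#' @return numeric matrix in [0, 1] with attributes `timestamps` and
#'   `depth_mm` when available.
#' @export
normalize_amode <- function(series) {
  if (inherits(series, "amode_series")) {
    m <- Mod(series$matrix)
    ts <- series$timestamps
    depth <- amode_depth_mm(series)
  } else {
    m <- Mod(series)
    ts <- NULL; depth <- NULL
  }
  mx <- max(m)
  if (!is.finite(mx) || mx == 0)
    stop("cannot normalise an all-zero series", call. = FALSE)
  out <- m / mx
  attr(out, "timestamps") <- ts
  attr(out, "depth_mm") <- depth
  out
}

#' Median signal within a depth band
#'
#' Per time column, the median of the normalised magnitude over the rows
#' whose depth falls in `depth_band_mm` (half-open interval).
#'
#' @param series an `amode_series` (normalised internally) or a matrix
#'   from [normalize_amode()].
#' @param depth_band_mm numeric length-2 interval (mm).
#' @return a [displacement_curve()] with `units = "a.u."`.
#' @export
band_median <- function(series, depth_band_mm) {
  if (inherits(series, "amode_series")) series <- normalize_amode(series)
  depth <- attr(series, "depth_mm")
  if (is.null(depth))
    stop("series has no depth axis; pass an amode_series", call. = FALSE)
  rows <- which(depth >= depth_band_mm[1] & depth < depth_band_mm[2])
  if (length(rows) == 0) stop("empty depth band", call. = FALSE)
  ts <- attr(series, "timestamps")
  if (is.null(ts)) ts <- seq_len(ncol(series)) - 1
  displacement_curve(ts, apply(series[rows, , drop = FALSE], 2, median),
                     reference = "band median", units = "a.u.")
}
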