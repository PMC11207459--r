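#' Sensor and displacement curve containers
#'
#' `pt_series()` holds a scalar Pilot-Tone amplitude per timestamp;
#' `displacement_curve()` holds a physical displacement (mm) or area
#' (mm^2) per timestamp.
#'
#' @param timestamps times (s), strictly increasing.
#' @param amplitude,value curve samples.
#' @param source_frequency_hz frequency the amplitude was read from (Hz).
#' @param reference semantic tag for the zero point (e.g. end-exhale
#'   minimum).
#' @param units unit label for `value`.
#' @return objects of class `pt_series` / `displacement_curve`.
#' @export
pt_series <- function(timestamps, amplitude, source_frequency_hz = NA_real_) {
  stopifnot(length(timestamps) == length(amplitude))
  if (any(!is.finite(amplitude)))
    stop("pilot-tone amplitudes must be finite", call. = FALSE)
  structure(list(timestamps = as.numeric(timestamps),
                 amplitude = as.numeric(amplitude),
                 source_frequency_hz = source_frequency_hz),
            class = "pt_series")
}

#' @rdname pt_series
#' @export
displacement_curve <- function(timestamps, value, reference = "end-exhale",
                               units = "mm") {
  stopifnot(length(timestamps) == length(value))
  if (any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  if (any(!is.finite(value)))
    stop("displacement values must be finite", call. = FALSE)
  structure(list(timestamps = as.numeric(timestamps),
                 value = as.numeric(value), reference = reference,
                 units = units),
            class = "displacement_curve")
}

#' @export
print.pt_series <- function(x, ...) {
  cat(sprintf("<pt_series> %d samples over %.2f s, amplitude %.3g..%.3g\n",
              length(x$amplitude), diff(range(x$timestamps)),
              min(x$amplitude), max(x$amplitude)))
  invisible(x)
}

#' @export
print.displacement_curve <- function(x, ...) {
  cat(sprintf("<displacement_curve> %d samples, %.2f..%.2f %s (ref: %s)\n",
              length(x$value), min(x$value), max(x$value), x$units,
              x$reference))
  invisible(x)
}

#' Export a curve to CSV (timestamp,value)
#'
#' @param curve a `pt_series` or `displacement_curve`.
#' @param path output file.
#' @export
write_curve_csv <- function(curve, path) {
  v <- if (inherits(curve, "pt_series")) curve$amplitude else curve$value
  write.csv(data.frame(timestamp = curve$timestamps, value = v),
            path, row.names = FALSE)
  invisible(path)
}
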