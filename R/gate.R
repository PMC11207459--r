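#' Gate k-space lines by motion state
#'
#' Removes k-space lines acquired during aberrant motion, either those
#' whose predicted displacement exceeds a threshold (e.g. 20 mm) or those
#' falling inside flagged event intervals (e.g. coughs). The retained
#' subset keeps the nominal spoke count for density compensation, and the
#' retention mask and fraction are attached as attributes.
#'
#' @param kspace a `kspace_series`.
#' @param disp a [displacement_curve()] defined over the acquisition
#'   (interpolated to line timestamps); may be `NULL` when only `events`
#'   are used.
#' @param threshold_mm keep lines with `|displacement| <= threshold_mm`.
#'   `Inf` disables amplitude gating.
#' @param events optional data.frame with `start`/`end` columns (s);
#'   lines with timestamps inside any interval are removed.
#' @return the gated `kspace_series` with attributes `retained` (logical
#'   per input line) and `retained_fraction`.
#' @export
gate_kspace <- function(kspace, disp = NULL, threshold_mm = Inf,
                        events = NULL) {
  ts <- kspace$timestamps
  keep <- rep(TRUE, length(ts))
  if (is.finite(threshold_mm)) {
    if (is.null(disp))
      stop("threshold gating needs a displacement curve", call. = FALSE)
    d <- interp_curve(disp$timestamps, disp$value, ts)
    keep <- keep & abs(d) <= threshold_mm
  }
  if (!is.null(events) && nrow(events) > 0)
    for (i in seq_len(nrow(events)))
      keep <- keep & !(ts >= events$start[i] & ts <= events$end[i])
  if (!any(keep))
    stop("gating rule removed every k-space line", call. = FALSE)
  out <- kspace
  if (length(dim(kspace$lines)) == 3L) {
    out$lines <- kspace$lines[, keep, , drop = FALSE]
  } else out$lines <- kspace$lines[, keep, drop = FALSE]
  out$angles <- kspace$angles[keep]
  out$timestamps <- ts[keep]
  out$ktraj <- list(kx = kspace$ktraj$kx[, keep, drop = FALSE],
                    ky = kspace$ktraj$ky[, keep, drop = FALSE])
  out$n_spokes_nominal <- kspace$n_spokes_nominal
  attr(out, "retained") <- keep
  attr(out, "retained_fraction") <- mean(keep)
  out
}

#' Convert event labels to time intervals
#'
#' Collapses per-sample trajectory event labels into a start/end table
#' for one label class, for use with [gate_kspace()].
#'
#' @param phantom a `motion_phantom`.
#' @param label event label (e.g. `"cough"`).
#' @return data.frame with `start` and `end` (s).
#' @export
event_intervals <- function(phantom, label = "cough") {
  tr <- phantom$trajectory
  sel <- tr$event_labels == label
  if (!any(sel)) return(data.frame(start = numeric(0), end = numeric(0)))
  r <- rle(sel)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  idx <- which(r$values)
  data.frame(start = tr$times[starts[idx]], end = tr$times[ends[idx]])
}
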