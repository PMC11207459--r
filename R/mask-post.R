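#' Post-process a binary segmentation mask
#'
#' Applies the two clean-up steps used on network predictions: fill all
#' enclosed non-foreground holes, then keep only the largest connected
#' foreground component (removing stray pixels and islands). The
#' operation is idempotent. An all-zero mask is returned unchanged with
#' attribute `empty_mask = TRUE`.
#'
#' @param mask binary (logical or 0/1) matrix.
#' @return logical matrix of the same shape.
#' @export
postprocess_mask <- function(mask) {
  m <- matrix(as.integer(as.logical(mask)), nrow(mask), ncol(mask))
  if (!all(m %in% c(0L, 1L))) stop("mask must be binary", call. = FALSE)
  if (sum(m) == 0) {
    out <- matrix(FALSE, nrow(mask), ncol(mask))
    attr(out, "empty_mask") <- TRUE
    return(out)
  }
  filled <- EBImage::fillHull(m)
  lab <- EBImage::bwlabel(filled)
  sizes <- tabulate(lab[lab > 0])
  out <- lab == which.max(sizes)
  attr(out, "empty_mask") <- FALSE
  out
}

#' Liver boundary displacement from a mask series
#'
#' For each frame the superior liver-lung boundary is taken as the
#' topmost foreground row in every column that contains mask, and the
#' frame's boundary position is the median of those rows. The positions
#' are converted to mm and referenced to the series minimum (end-exhale
#' baseline). Frames with an empty mask are marked missing, linearly
#' interpolated, and counted in the `qc` attribute.
#'
#' @param masks logical array (H x W x T) or list of masks.
#' @param pixel_size_mm pixel size (mm).
#' @param timestamps frame times (s); defaults to frame index.
#' @return a [displacement_curve()] with attribute `qc` (list with
#'   `n_missing`).
#' @export
extract_boundary_displacement <- function(masks, pixel_size_mm,
                                          timestamps = NULL) {
  if (is.list(masks)) masks <- simplify2array(masks)
  stopifnot(length(dim(masks)) == 3L)
  n_t <- dim(masks)[3]
  if (is.null(timestamps)) timestamps <- seq_len(n_t) - 1
  pos <- vapply(seq_len(n_t), function(k) {
    m <- masks[, , k]
    cols <- which(colSums(m) > 0)
    if (length(cols) == 0) return(NA_real_)
    top_rows <- vapply(cols, function(j) which(m[, j] != 0)[1], 0L)
    median(top_rows)
  }, 0)
  n_missing <- sum(is.na(pos))
  if (n_missing == n_t)
    stop("every mask in the series is empty", call. = FALSE)
  if (n_missing > 0)
    pos <- approx(timestamps[!is.na(pos)], pos[!is.na(pos)],
                  xout = timestamps, rule = 2)$y
  value <- (pos - min(pos)) * pixel_size_mm
  out <- displacement_curve(timestamps, value, reference = "end-exhale minimum")
  attr(out, "qc") <- list(n_missing = n_missing)
  out
}
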