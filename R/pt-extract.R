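#' Extract the Pilot-Tone amplitude from raw k-space
#'
#' After a Fourier transform along the readout direction, the Pilot-Tone
#' appears as a sharp peak in the spectrum of every k-space line. For
#' each line the peak magnitude is located within a small search window
#' around the expected readout-frequency bin and recorded at the line's
#' timestamp. Multi-channel data are reduced to the channel with the
#' largest mean peak magnitude. The extraction uses magnitudes only, so
#' it is invariant to a global k-space phase.
#'
#' @param kspace a `kspace_series`.
#' @param expected_offset_hz expected tone offset (Hz); defaults to the
#'   sequence's `pt_offset_hz`.
#' @param search_halfwidth_bins half-width of the peak search window
#'   (readout-frequency bins).
#' @param floor_ratio minimum peak-to-local-background magnitude ratio;
#'   if more than half the lines fall below it a "tone not detected"
#'   error is raised.
#' @return a [pt_series()].
#' @export
extract_pt_signal <- function(kspace, expected_offset_hz = kspace$seq$pt_offset_hz,
                              search_halfwidth_bins = 3L, floor_ratio = 3) {
  seqp <- kspace$seq
  fs <- readout_fs(seqp)
  n <- seqp$n_readout
  freqs <- ((seq_len(n) - 1) - n / 2) * fs / n   # after fftshift
  bin0 <- which.min(abs(freqs - expected_offset_hz))
  if (abs(freqs[bin0] - expected_offset_hz) > fs / n)
    stop("expected offset does not map to a valid readout bin", call. = FALSE)
  win <- pmax(1L, bin0 - search_halfwidth_bins):pmin(n, bin0 + search_halfwidth_bins)
  bg_lo <- search_halfwidth_bins + 1L
  bg <- setdiff(pmax(1L, bin0 - 4L * bg_lo):pmin(n, bin0 + 4L * bg_lo), win)

  channel_peaks <- function(lines) {
    spec <- Mod(mvfft(lines))
    ## reorder to fftshifted frequency axis
    spec <- spec[c((n / 2 + 1):n, 1:(n / 2)), , drop = FALSE]
    peak <- apply(spec[win, , drop = FALSE], 2, max)
    backg <- apply(spec[bg, , drop = FALSE], 2, median)
    list(peak = peak, ratio = peak / pmax(backg, .Machine$double.eps))
  }

  nd <- length(dim(kspace$lines))
  if (nd == 3L) {
    per_ch <- lapply(seq_len(dim(kspace$lines)[3]),
                     function(ch) channel_peaks(kspace$lines[, , ch]))
    best <- which.max(vapply(per_ch, function(p) mean(p$peak), 0))
    res <- per_ch[[best]]
  } else res <- channel_peaks(kspace$lines)

  if (mean(res$ratio < floor_ratio) > 0.5)
    stop("tone not detected: spectral peak indistinct on most lines",
         call. = FALSE)
  pt_series(kspace$timestamps, res$peak, expected_offset_hz)
}
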