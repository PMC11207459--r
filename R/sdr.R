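#' Simulate a software-defined-radio IQ stream carrying the Pilot-Tone
#'
#' Complex baseband samples `s(n) = a(n/fs) exp(2i pi f_pt n/fs) + e`,
#' where the amplitude `a(.)` is linearly interpolated from the supplied
#' respiration curve and `e` is complex Gaussian noise. The native
#' sampling rate is 3 MHz; a decimated rate can be configured for long
#' desk-scale runs.
#'
#' @param pt_amp_curve a function of time (s) or a list with
#'   `timestamps`/`value` (or `amplitude`) giving `a(t)`.
#' @param f_pt_hz tone offset from the receiver centre (Hz);
#'   `|f_pt_hz| < fs_hz/2` or an aliasing error is raised.
#' @param fs_hz sampling rate (Hz).
#' @param duration_s stream length (s); defaults to the curve span.
#' @param noise_sd complex noise standard deviation per component.
#' @param seed noise seed.
#' @return an `iq_stream`: `samples` (complex), `fs_hz`, `f_pt_hz`.
#' @export
simulate_sdr_stream <- function(pt_amp_curve, f_pt_hz, fs_hz = 3e6,
                                duration_s = NULL, noise_sd = 0,
                                seed = 0L) {
  if (abs(f_pt_hz) >= fs_hz / 2)
    stop("tone aliases: |f_pt_hz| must be below fs_hz/2", call. = FALSE)
  if (is.function(pt_amp_curve)) {
    a_at <- pt_amp_curve
    if (is.null(duration_s))
      stop("duration_s required with a function curve", call. = FALSE)
  } else {
    v <- if (!is.null(pt_amp_curve$value)) pt_amp_curve$value
         else pt_amp_curve$amplitude
    a_at <- function(t) interp_curve(pt_amp_curve$timestamps, v, t)
    if (is.null(duration_s)) duration_s <- max(pt_amp_curve$timestamps)
  }
  n <- floor(duration_s * fs_hz)
  t <- (seq_len(n) - 1) / fs_hz
  s <- a_at(t) * exp(2i * pi * f_pt_hz * t)
  if (noise_sd > 0)
    s <- s + with_seed(seed, complex(real = rnorm(n, sd = noise_sd),
                                     imaginary = rnorm(n, sd = noise_sd)))
  structure(list(samples = s, fs_hz = fs_hz, f_pt_hz = f_pt_hz),
            class = "iq_stream")
}

#' Demodulate the Pilot-Tone amplitude from an IQ stream
#'
#' An FFT is taken over non-overlapping groups of `block` consecutive
#' samples (5120 at 3 MHz, i.e. ~585.94 blocks/s); the spectrum
#' magnitude at the bin nearest the tone frequency gives one amplitude
#' per block, timestamped at the block centre; a median filter of the
#' configured order smooths the series. A trailing partial block is
#' dropped.
#'
#' @param iq an `iq_stream`.
#' @param f_pt_hz tone frequency (Hz); defaults to the stream's.
#' @param block samples per FFT group.
#' @param filter_order median filter order (odd).
#' @return a [pt_series()].
#' @export
demodulate_sdr <- function(iq, f_pt_hz = iq$f_pt_hz, block = 5120L,
                           filter_order = 9L) {
  if (abs(f_pt_hz) >= iq$fs_hz / 2)
    stop("tone aliases: |f_pt_hz| must be below fs/2", call. = FALSE)
  n <- length(iq$samples)
  if (n < block) stop("stream shorter than one FFT block", call. = FALSE)
  n_blocks <- n %/% block
  m <- matrix(iq$samples[seq_len(n_blocks * block)], block, n_blocks)
  ## FFT bin nearest the tone (frequencies k*fs/block, aliased)
  k <- round(f_pt_hz / iq$fs_hz * block) %% block
  w <- exp(-2i * pi * k * (seq_len(block) - 1) / block)
  amp <- Mod(as.vector(crossprod(w, m)))
  ts <- ((seq_len(n_blocks) - 0.5) * block) / iq$fs_hz
  if (filter_order > 1 && n_blocks >= filter_order)
    amp <- as.numeric(runmed(amp, filter_order, endrule = "median"))
  pt_series(ts, amp, f_pt_hz)
}
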