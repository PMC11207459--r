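#' Simulate a golden-angle radial k-space acquisition
#'
#' Each spoke is the exact forward non-uniform Fourier transform of the
#' phantom image at the spoke's acquisition time (spoke k is acquired at
#' `(k-1) * TR`), on a radial trajectory with golden-angle (111.246
#' degree) increments. Motion states are quantised to 0.05 mm of liver
#' displacement and rendered images cached, so a breathing phantom costs
#' one rasterisation per distinct motion state.
#'
#' @param phantom a [make_breathing_phantom()] object.
#' @param seq a [seq_params_radial()] object.
#' @param seed seed for the measurement noise.
#' @param noise_sd complex noise standard deviation per sample (the
#'   noiseless spoke magnitudes are of order the image sum).
#' @return a `kspace_series`: `lines` (complex, n_readout x n_spokes),
#'   `angles` (rad), `ktraj` (list of kx, ky in cycles/FOV),
#'   `timestamps` (s), `channel_ids`, `seq`.
#' @export
simulate_radial_kspace <- function(phantom, seq = seq_params_radial(),
                                   seed = phantom$seed + 2L, noise_sd = 0) {
  if (seq$n_spokes < 1) stop_config("n_spokes must be >= 1")
  N <- seq$matrix_size
  n_ro <- seq$n_readout
  angles <- spoke_angles(seq$n_spokes)
  rho <- spoke_radii(n_ro, N)
  ts <- (seq_len(seq$n_spokes) - 1) * seq$tr_ms / 1e3
  if (max(ts) > phantom$config$duration_s)
    stop("acquisition outlasts the phantom trajectory", call. = FALSE)

  d <- traj_at(phantom, "resp_displacement", ts)
  key <- sprintf("%.2f", round(d / 0.05) * 0.05)
  cache <- new.env(parent = emptyenv())
  lines <- matrix(0 + 0i, n_ro, seq$n_spokes)
  for (k in seq_len(seq$n_spokes)) {
    img <- get0(key[k], envir = cache)
    if (is.null(img)) {
      img <- render_phantom_frame(phantom, ts[k])$image
      assign(key[k], img, envir = cache)
    }
    lines[, k] <- ndft_spoke(img, rho, angles[k], N)
  }
  if (noise_sd > 0)
    lines <- lines + with_seed(seed, {
      matrix(complex(real = rnorm(length(lines), sd = noise_sd),
                     imaginary = rnorm(length(lines), sd = noise_sd)),
             n_ro, seq$n_spokes)
    })
  new_kspace_series(lines, angles, ts, seq)
}

#' Construct a k-space series
#'
#' Low-level constructor used by the simulator and the container reader.
#'
#' @param lines complex matrix (n_readout x n_lines) or 3D array with a
#'   channel dimension.
#' @param angles spoke angles (rad).
#' @param timestamps per-line acquisition times (s).
#' @param seq a [seq_params()] object.
#' @param channel_ids receive-channel identifiers.
#' @param n_spokes_nominal nominal full-acquisition spoke count (kept
#'   across gating).
#' @return a `kspace_series`.
#' @export
new_kspace_series <- function(lines, angles, timestamps, seq,
                              channel_ids = 1L, n_spokes_nominal = NULL) {
  rho <- spoke_radii(seq$n_readout, seq$matrix_size)
  structure(list(
    lines = lines, angles = angles,
    ktraj = list(kx = outer(rho, cos(angles)), ky = outer(rho, sin(angles))),
    timestamps = timestamps, channel_ids = channel_ids, seq = seq,
    n_spokes_nominal = if (is.null(n_spokes_nominal)) length(angles)
                       else n_spokes_nominal),
    class = "kspace_series")
}

#' @export
print.kspace_series <- function(x, ...) {
  cat(sprintf("<kspace_series> %d lines x %d samples, %.1f s\n",
              ncol(kspace_lines_2d(x)), nrow(kspace_lines_2d(x)),
              diff(range(x$timestamps))))
  invisible(x)
}

#' Inject a Pilot-Tone into raw k-space
#'
#' Adds to every readout line a complex exponential at the configured
#' frequency offset with amplitude `a(t) = a0 + gain * d(t) + e`,
#' `e ~ N(0, noise_sd)`, where `d(t)` is a displacement (or any surrogate)
#' curve sampled at the line timestamp. The tone frequency must fall
#' inside the sampled readout spectrum but outside the imaging band,
#' mirroring how spectral overlap between tone and image is avoided in
#' practice; violating that raises a "spectral overlap" error.
#'
#' @param kspace a `kspace_series`.
#' @param pt_amp_curve either a function of time (s) or a list with
#'   `timestamps` and `value` fields giving `d(t)`.
#' @param pt_offset_hz tone offset from the centre frequency (Hz);
#'   defaults to the sequence's `pt_offset_hz`.
#' @param a0 baseline tone amplitude (k-space units).
#' @param gain amplitude modulation per unit of `d(t)`.
#' @param noise_sd amplitude noise standard deviation.
#' @param seed seed for the amplitude noise.
#' @return the `kspace_series` with the tone added; the injected per-line
#'   amplitudes are attached as attribute `"pt_amplitude"`.
#' @export
inject_pilot_tone <- function(kspace, pt_amp_curve,
                              pt_offset_hz = kspace$seq$pt_offset_hz,
                              a0 = 1, gain = 0, noise_sd = 0, seed = 0L) {
  seqp <- kspace$seq
  fs <- readout_fs(seqp)
  if (abs(pt_offset_hz) >= fs / 2)
    stop("pilot-tone offset aliases: |offset| must be < half the sampled readout bandwidth",
         call. = FALSE)
  if (abs(pt_offset_hz) <= imaging_band_hz(seqp) / 2)
    stop("spectral overlap: pilot-tone offset falls inside the imaging band",
         call. = FALSE)
  d_at <- if (is.function(pt_amp_curve)) pt_amp_curve
    else function(t) interp_curve(pt_amp_curve$timestamps, pt_amp_curve$value, t)
  ts <- kspace$timestamps
  amp <- a0 + gain * d_at(ts)
  if (noise_sd > 0)
    amp <- amp + with_seed(seed, rnorm(length(amp), sd = noise_sd))
  n_ro <- seqp$n_readout
  t_samp <- (seq_len(n_ro) - 1) / fs
  lines <- kspace_lines_2d(kspace)
  ## continuous-phase tone across lines
  tone_unit <- exp(2i * pi * pt_offset_hz * t_samp)
  phase_line <- exp(2i * pi * pt_offset_hz * ts)
  lines <- lines + tone_unit %o% (amp * phase_line)
  out <- kspace
  out$lines <- lines
  attr(out, "pt_amplitude") <- amp
  out
}
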