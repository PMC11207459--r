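#' MR sequence parameters
#'
#' Container for the acquisition parameters used by the simulators.
#' Defaults follow the fast 2D bSSFP calibration protocol (TR 2.26 ms,
#' TE 1.13 ms, 128 matrix, 17.69 frames/s, 1955 Hz/pixel); use
#' [seq_params_radial()] for the radial GRE testing protocol.
#'
#' @param tr_ms repetition time (ms).
#' @param te_ms echo time (ms).
#' @param matrix_size image matrix (pixels, square).
#' @param frame_rate_hz image frame rate (frames/s).
#' @param pixel_bandwidth_hz readout bandwidth per pixel (Hz/pixel).
#' @param n_readout readout samples per line/spoke (2x oversampled).
#' @param n_spokes number of radial spokes (radial protocol).
#' @param pt_offset_hz Pilot-Tone offset from the imaging centre
#'   frequency (Hz); must fall outside the imaging band.
#' @param center_freq_hz scanner centre frequency (Hz).
#' @return an object of class `sequence_params`.
#' @export
seq_params <- function(tr_ms = 2.26, te_ms = 1.13, matrix_size = 128L,
                       frame_rate_hz = 17.69, pixel_bandwidth_hz = 1955,
                       n_readout = 2L * matrix_size, n_spokes = 402L,
                       pt_offset_hz = 180e3, center_freq_hz = 23.59e6) {
  if (!(tr_ms > te_ms && te_ms > 0))
    stop_config("sequence requires tr_ms > te_ms > 0")
  check_positive(frame_rate_hz, "frame_rate_hz")
  check_positive(pixel_bandwidth_hz, "pixel_bandwidth_hz")
  structure(list(tr_ms = tr_ms, te_ms = te_ms,
                 matrix_size = as.integer(matrix_size),
                 frame_rate_hz = frame_rate_hz,
                 pixel_bandwidth_hz = pixel_bandwidth_hz,
                 n_readout = as.integer(n_readout),
                 n_spokes = as.integer(n_spokes),
                 pt_offset_hz = pt_offset_hz,
                 center_freq_hz = center_freq_hz),
            class = "sequence_params")
}

#' @rdname seq_params
#' @export
seq_params_radial <- function(tr_ms = 3.57, te_ms = 1.69, matrix_size = 128L,
                              pixel_bandwidth_hz = 500, n_spokes = 402L,
                              pt_offset_hz = 48e3, ...) {
  seq_params(tr_ms = tr_ms, te_ms = te_ms, matrix_size = matrix_size,
             pixel_bandwidth_hz = pixel_bandwidth_hz, n_spokes = n_spokes,
             pt_offset_hz = pt_offset_hz, ...)
}

## Total sampled readout bandwidth (Hz): n_readout samples at the pixel
## bandwidth. With 2x readout oversampling the central matrix_size pixels
## span the imaging band and the outer half is PT headroom.
readout_fs <- function(seq) seq$n_readout * seq$pixel_bandwidth_hz
imaging_band_hz <- function(seq) seq$matrix_size * seq$pixel_bandwidth_hz
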