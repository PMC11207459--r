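#' A-mode transducer parameters
#'
#' @param fs_hz RF sampling rate (Hz).
#' @param pulse_freq_hz transducer centre frequency (Hz, 1 MHz).
#' @param sound_speed_m_s assumed speed of sound (m/s).
#' @param prf_hz pulse repetition (column) rate (Hz).
#' @param depth_window_mm maximum recorded depth (mm).
#' @param pulse_sigma_s Gaussian envelope width of the Gabor pulse (s).
#' @param attenuation_per_mm depth attenuation coefficient (1/mm).
#' @param resp_depth_scale interface displacement per mm of liver
#'   respiration displacement (mm/mm).
#' @param noise_sd additive RF noise standard deviation.
#' @return named list of class `us_params`.
#' @export
us_params <- function(fs_hz = 20e6, pulse_freq_hz = 1e6,
                      sound_speed_m_s = 1540, prf_hz = 100,
                      depth_window_mm = 110, pulse_sigma_s = 0.6e-6,
                      attenuation_per_mm = 0.01, resp_depth_scale = 0.3,
                      noise_sd = 0.005) {
  if (fs_hz <= 2 * pulse_freq_hz)
    stop_config("fs_hz must exceed twice the pulse frequency")
  structure(as.list(environment()), class = "us_params")
}

## reflector depth trajectories (mm) given the phantom motion state.
## The posterior bladder wall sits a fixed multiple of the vertical
## semi-axis deeper than the anterior wall, so the echo separation
## encodes the bladder geometry irrespective of the subject.
reflector_depths_at <- function(phantom, us, t, refl = phantom$reflectors) {
  g <- phantom$organ_geometry
  d <- traj_at(phantom, "resp_displacement", t)
  b_t <- traj_at(phantom, "bladder_b", t)
  b0 <- phantom$config$bladder_semiaxes_mm[2]
  z_front <- g$bladder_front_depth_mm + 0.1 * d + 0.55 * (b0 - b_t)
  vapply(seq_len(nrow(refl)), function(r) {
    z0 <- refl$depth_mm[r]
    switch(refl$mode[r],
      static = z0,
      resp = z0 + us$resp_depth_scale * d,
      anti = z0 - us$resp_depth_scale * d,
      bladder_front = z_front,
      bladder_back = z_front + g$bladder_sep_per_b * b_t,
      z0)
  }, 0)
}

#' Simulate raw A-mode ultrasound echo data
#'
#' Each time column is the superposition of Gabor pulses (1 MHz cosine
#' carrier under a Gaussian envelope) centred at the round-trip sample
#' index `round(2 z fs / c)` of every reflector, with depth-dependent
#' exponential attenuation. Interface groups move with respiration, one
#' group in anti-phase, and the bladder-wall reflectors shift with
#' pelvic contractions and mid-sagittal area.
#'
#' @param phantom a [make_breathing_phantom()] object.
#' @param us a [us_params()] list.
#' @param seed seed for the RF noise.
#' @return an `amode_series` with the real RF matrix in `$rf`
#'   (depth samples x time columns); pass it to [reconstruct_amode()].
#' @export
simulate_amode <- function(phantom, us = us_params(), seed = phantom$seed + 3L) {
  n_depth <- floor(2 * us$depth_window_mm / 1e3 * us$fs_hz / us$sound_speed_m_s)
  ts <- seq(0, phantom$config$duration_s, by = 1 / us$prf_hz)
  refl <- rbind(phantom$reflectors,
                if (!is.null(phantom$scatterers)) phantom$scatterers)
  if (nrow(refl) > 0 && any(refl$depth_mm > us$depth_window_mm))
    stop("reflector deeper than the recorded depth window", call. = FALSE)
  t_axis <- seq_len(n_depth) / us$fs_hz
  rf <- matrix(0, n_depth, length(ts))
  if (nrow(refl) > 0) {
    half <- ceiling(4 * us$pulse_sigma_s * us$fs_hz)
    for (j in seq_along(ts)) {
      z <- reflector_depths_at(phantom, us, ts[j], refl)
      col <- numeric(n_depth)
      for (r in seq_along(z)) {
        tc <- 2 * z[r] / 1e3 / us$sound_speed_m_s
        ic <- round(tc * us$fs_hz)
        lo <- max(1L, ic - half); hi <- min(n_depth, ic + half)
        if (lo > hi) next
        tt <- t_axis[lo:hi] - tc
        col[lo:hi] <- col[lo:hi] +
          refl$amp[r] * exp(-us$attenuation_per_mm * z[r]) *
          exp(-tt^2 / (2 * us$pulse_sigma_s^2)) *
          cos(2 * pi * us$pulse_freq_hz * tt)
      }
      rf[, j] <- col
    }
  }
  if (us$noise_sd > 0)
    rf <- rf + with_seed(seed,
      matrix(rnorm(length(rf), sd = us$noise_sd), nrow(rf), ncol(rf)))
  structure(list(rf = rf, matrix = NULL, fs_hz = us$fs_hz,
                 pulse_freq_hz = us$pulse_freq_hz,
                 sound_speed_m_s = us$sound_speed_m_s,
                 timestamps = ts, us = us),
            class = "amode_series")
}
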