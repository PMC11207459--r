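#' Time-of-Flight camera parameters
#'
#' @param frame_rate_hz frame rate (frames/s; the camera records at 5).
#' @param resolution sensor pixels (rows, cols).
#' @param camera_height_mm distance from camera to the couch plane (mm).
#' @param noise_sd_mm per-pixel depth noise (mm).
#' @param invalid_fraction expected fraction of overexposed pixels per
#'   frame where distance cannot be discerned.
#' @return named list of class `tof_params`.
#' @export
tof_params <- function(frame_rate_hz = 5, resolution = c(171L, 224L),
                       camera_height_mm = 800, noise_sd_mm = 0.5,
                       invalid_fraction = 0.1) {
  check_positive(frame_rate_hz, "frame_rate_hz")
  structure(as.list(environment()), class = "tof_params")
}

## abdominal surface height above the couch at each pixel (mm): a static
## smooth bump (body shape) plus the respiratory surface displacement,
## which raises and lowers the whole visible surface rigidly, so the
## frame-averaged waveform amplitude equals the programmed excursion
surface_height_map <- function(phantom, cam, s_t) {
  g <- phantom$organ_geometry
  H <- cam$resolution[1]; W <- cam$resolution[2]
  u <- (row(matrix(0, H, W)) - (H + 1) / 2) / (H / 2)
  v <- (col(matrix(0, H, W)) - (W + 1) / 2) / (W / 2)
  bump <- exp(-(u^2 + v^2) / (2 * g$surface_bump_sigma^2))
  g$surface_height_mm + g$surface_bump_mm * bump + s_t
}

#' Simulate Time-of-Flight depth frames
#'
#' Per-pixel Z is the camera height minus the surface height at the
#' frame timestamp, plus Gaussian noise; a random fraction of pixels per
#' frame is marked invalid (overexposed pixels whose distance cannot be
#' discerned).
#'
#' @param phantom a [make_breathing_phantom()] object.
#' @param cam a [tof_params()] list.
#' @param seed seed for noise and invalid-pixel draws.
#' @return a `depth_frames` object: `frames` (Z in mm, H x W x T),
#'   `validity` (logical, same shape), `timestamps` (s), `frame_rate_hz`.
#' @export
simulate_tof_frames <- function(phantom, cam = tof_params(),
                                seed = phantom$seed + 4L) {
  g <- phantom$organ_geometry
  max_surf <- g$surface_height_mm + g$surface_bump_mm +
    max(abs(phantom$trajectory$surface_displacement))
  if (cam$camera_height_mm <= max_surf)
    stop_config("camera height must exceed the maximum surface height")
  n_frames <- floor(phantom$config$duration_s * cam$frame_rate_hz)
  ts <- (seq_len(n_frames) - 1) / cam$frame_rate_hz
  H <- cam$resolution[1]; W <- cam$resolution[2]
  frames <- array(0, c(H, W, n_frames))
  validity <- array(TRUE, c(H, W, n_frames))
  s <- traj_at(phantom, "surface_displacement", ts)
  with_seed(seed, {
    for (k in seq_len(n_frames)) {
      z <- cam$camera_height_mm - surface_height_map(phantom, cam, s[k])
      if (cam$noise_sd_mm > 0)
        z <- z + matrix(rnorm(H * W, sd = cam$noise_sd_mm), H, W)
      frames[, , k] <- z
      if (cam$invalid_fraction > 0)
        validity[, , k] <- matrix(runif(H * W) >= cam$invalid_fraction, H, W)
    }
  })
  structure(list(frames = frames, validity = validity, timestamps = ts,
                 frame_rate_hz = cam$frame_rate_hz),
            class = "depth_frames")
}
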