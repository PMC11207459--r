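#' Phantom and motion configuration
#'
#' Builds the configuration list consumed by [make_breathing_phantom()].
#' Defaults emulate a free-breathing abdominal exam: ~10 mm peak-to-peak
#' superior-inferior liver excursion with a 4 s breathing period, a body
#' surface that rises and falls by a few millimetres, occasional deep
#' breaths and coughs, and (for the pelvic variant) pelvic-floor
#' contractions that transiently shrink the mid-sagittal bladder area.
#'
#' @param region `"abdomen"` (liver/lung anatomy) or `"pelvis"` (bladder).
#' @param grid_shape image matrix size in pixels.
#' @param pixel_size_mm in-plane pixel size (mm).
#' @param duration_s length of the simulated acquisition (s).
#' @param sample_rate_hz trajectory sampling rate (Hz).
#' @param breath_period_s mean breathing period (s).
#' @param resp_amplitude_mm peak-to-peak liver superior-inferior excursion
#'   during normal breathing (mm).
#' @param amp_jitter,period_jitter per-cycle fractional variability.
#' @param drift_amplitude_mm amplitude of a slow baseline drift (mm).
#' @param drift_period_s period of the baseline drift (s).
#' @param surface_scale ratio of body-surface to liver excursion.
#' @param deep_breath_times,cough_times,contraction_times event onset times
#'   (s); `NULL` places the default schedule (one deep breath, two coughs,
#'   two pelvic contractions) scaled to `duration_s`.
#' @param deep_breath_factor amplitude multiplier for deep-breath cycles.
#' @param cough_amplitude_mm,cough_duration_s cough transient shape.
#' @param contraction_depth fractional bladder-area reduction at the peak
#'   of a pelvic contraction.
#' @param contraction_duration_s duration of each contraction (s).
#' @param bladder_semiaxes_mm bladder ellipse semi-axes (mm) at rest.
#' @return a named list of class `phantom_config`.
#' @export
phantom_config <- function(region = c("abdomen", "pelvis"),
                           grid_shape = c(128L, 128L),
                           pixel_size_mm = 2.34,
                           duration_s = 30,
                           sample_rate_hz = 50,
                           breath_period_s = 4,
                           resp_amplitude_mm = 10,
                           amp_jitter = 0.05,
                           period_jitter = 0.05,
                           drift_amplitude_mm = 0.5,
                           drift_period_s = 60,
                           surface_scale = 0.5,
                           deep_breath_times = NULL,
                           cough_times = NULL,
                           contraction_times = NULL,
                           deep_breath_factor = 2.5,
                           cough_amplitude_mm = 30,
                           cough_duration_s = 0.45,
                           contraction_depth = 0.35,
                           contraction_duration_s = 2.5,
                           bladder_semiaxes_mm = c(46.8, 35.1)) {
  region <- match.arg(region)
  check_positive(pixel_size_mm, "pixel_size_mm")
  check_positive(duration_s, "duration_s")
  check_positive(sample_rate_hz, "sample_rate_hz")
  check_positive(breath_period_s, "breath_period_s")
  if (resp_amplitude_mm < 0) stop_config("`resp_amplitude_mm` must be >= 0")
  ## protocol defaults: the abdominal (liver) acquisition includes 1-2
  ## coughs and deep breaths; the pelvic acquisition is normal breathing
  ## with occasional pelvic-floor contractions only
  if (is.null(deep_breath_times))
    deep_breath_times <- if (region == "abdomen") 0.40 * duration_s
                         else numeric(0)
  if (is.null(cough_times))
    cough_times <- if (region == "abdomen") c(0.62, 0.68) * duration_s
                   else numeric(0)
  if (is.null(contraction_times))
    contraction_times <- c(0.25, 0.80) * duration_s
  structure(list(
    region = region, grid_shape = as.integer(grid_shape),
    pixel_size_mm = pixel_size_mm, duration_s = duration_s,
    sample_rate_hz = sample_rate_hz, breath_period_s = breath_period_s,
    resp_amplitude_mm = resp_amplitude_mm, amp_jitter = amp_jitter,
    period_jitter = period_jitter, drift_amplitude_mm = drift_amplitude_mm,
    drift_period_s = drift_period_s, surface_scale = surface_scale,
    deep_breath_times = deep_breath_times, cough_times = cough_times,
    contraction_times = contraction_times,
    deep_breath_factor = deep_breath_factor,
    cough_amplitude_mm = cough_amplitude_mm,
    cough_duration_s = cough_duration_s,
    contraction_depth = contraction_depth,
    contraction_duration_s = contraction_duration_s,
    bladder_semiaxes_mm = bladder_semiaxes_mm
  ), class = "phantom_config")
}

## Cycle-wise asymmetric respiration waveform: within each breathing cycle
## displacement is amp * sin(pi*u)^4, giving a long end-exhale plateau and a
## brief inhalation peak. Per-cycle amplitude/period jitter is seeded.
make_motion_trajectory <- function(config) {
  times <- seq(0, config$duration_s, by = 1 / config$sample_rate_hz)
  n <- length(times)
  resp <- numeric(n)
  labels <- rep("normal", n)

  ## breathing cycles with jitter; deep breaths scale a whole cycle
  t0 <- 0
  while (t0 < config$duration_s) {
    per <- config$breath_period_s *
      (1 + config$period_jitter * stats::rnorm(1))
    per <- max(per, 0.5 * config$breath_period_s)
    amp <- config$resp_amplitude_mm *
      (1 + config$amp_jitter * stats::rnorm(1))
    is_deep <- any(config$deep_breath_times >= t0 &
                     config$deep_breath_times < t0 + per)
    if (is_deep) amp <- amp * config$deep_breath_factor
    sel <- times >= t0 & times < t0 + per
    u <- (times[sel] - t0) / per
    resp[sel] <- amp * sin(pi * u)^4
    if (is_deep) labels[sel] <- "deep_breath"
    t0 <- t0 + per
  }

  ## slow baseline drift
  resp <- resp + config$drift_amplitude_mm *
    sin(2 * pi * times / config$drift_period_s)

  ## cough transients override the respiratory state
  for (tc in config$cough_times) {
    sel <- times >= tc & times < tc + config$cough_duration_s
    if (!any(sel)) next
    u <- (times[sel] - tc) / config$cough_duration_s
    resp[sel] <- resp[sel] + config$cough_amplitude_mm * sin(pi * u)^2
    labels[sel] <- "cough"
  }

  surface <- config$surface_scale * resp

  ## bladder geometry: pelvic contractions squeeze the vertical
  ## (anterior-posterior) semi-axis b; the horizontal semi-axis keeps a
  ## fixed aspect ratio plus a small respiratory modulation, so the
  ## mid-sagittal area pi*a*b dips by `contraction_depth` at full squeeze
  contraction <- numeric(n)
  for (tc in config$contraction_times) {
    sel <- times >= tc & times < tc + config$contraction_duration_s
    if (!any(sel)) next
    u <- (times[sel] - tc) / config$contraction_duration_s
    contraction[sel] <- pmax(contraction[sel], sin(pi * u)^2)
    labels[sel] <- ifelse(labels[sel] == "normal", "pelvic_contraction",
                          labels[sel])
  }
  a0 <- config$bladder_semiaxes_mm[1]
  b0 <- config$bladder_semiaxes_mm[2]
  m <- 1 + 0.005 * resp / max(config$resp_amplitude_mm, 1)
  bladder_b <- b0 * sqrt(pmax(1 - config$contraction_depth * contraction, 0.01))
  bladder_a <- (a0 / b0) * bladder_b * m^2
  area <- pi * bladder_a * bladder_b

  structure(list(times = times, resp_displacement = resp,
                 surface_displacement = surface, bladder_area = area,
                 bladder_a = bladder_a, bladder_b = bladder_b,
                 contraction = contraction, event_labels = labels),
            class = "motion_trajectory")
}

#' Generate a breathing motion phantom
#'
#' Creates a parametric 2D anatomy (lung, liver with vessels, or a pelvic
#' field of view with an elliptical bladder) together with seeded motion
#' trajectories: superior-inferior liver displacement, anterior surface
#' displacement, mid-sagittal bladder area, and per-sample event labels
#' (`normal`, `deep_breath`, `cough`, `pelvic_contraction`). The default
#' event schedule contains at least one deep breath and one cough.
#'
#' @param config a [phantom_config()] list.
#' @param seed integer seed; identical seed and config give bit-identical
#'   trajectories.
#' @return an object of class `motion_phantom` with fields `config`,
#'   `trajectory`, `organ_geometry` and `reflectors` (A-mode interface
#'   table: rest depth in mm, echo amplitude, and motion coupling mode).
#' @export
make_breathing_phantom <- function(config = phantom_config(), seed = 0L) {
  if (!inherits(config, "phantom_config"))
    stop_config("`config` must come from phantom_config()")
  traj <- with_seed(seed, make_motion_trajectory(config))

  fov <- config$grid_shape * config$pixel_size_mm
  geom <- list(
    fov_mm = fov,
    body_cols_mm = c(0.08, 0.92) * fov[2],
    ## liver dome: superior boundary row (mm) as a parabola in column
    liver_boundary_mm = 0.35 * fov[1],
    liver_dome_mm = 14,
    liver_thickness_mm = 0.40 * fov[1],
    liver_cols_mm = c(0.15, 0.85) * fov[2],
    vessel_centers_mm = rbind(c(0.52, 0.35), c(0.62, 0.60), c(0.72, 0.48)) *
      matrix(fov, nrow = 3, ncol = 2, byrow = TRUE),
    vessel_radius_mm = c(4.5, 6.0, 3.5),
    bladder_center_mm = c(0.55, 0.50) * fov,
    bladder_semiaxes_mm = config$bladder_semiaxes_mm,
    ## A-mode bladder-wall geometry: the anterior wall sits at a fixed
    ## rest depth; the posterior wall echo is separated from it by a
    ## constant multiple of the vertical semi-axis (depth-axis surrogate)
    bladder_front_depth_mm = 60,
    bladder_sep_per_b = 1.1,
    ## ToF surface: camera looks down on a smooth abdominal bump
    surface_height_mm = 120,
    surface_bump_mm = 40,
    surface_bump_sigma = 0.35
  )

  ## A-mode reflector train (depths at rest, mm). Coupling modes:
  ##  static, resp (moves with respiration), anti (anti-phase group),
  ##  bladder_front / bladder_back (anterior / posterior bladder wall).
  reflectors <- data.frame(
    depth_mm = c(5, 15, 25, 40, 50, geom$bladder_front_depth_mm,
                 geom$bladder_front_depth_mm +
                   geom$bladder_sep_per_b * config$bladder_semiaxes_mm[2],
                 107),
    amp = c(0.3, 0.8, 0.9, 0.85, 0.8, 0.95, 0.9, 0.4),
    mode = c("static", "resp", "resp", "anti", "anti", "bladder_front",
             "bladder_back", "static"),
    stringsAsFactors = FALSE
  )

  ## diffuse scatterers emulating tissue speckle in the abdominal wall
  ## and mid-depth tissue (superficial tissue follows respiration, the
  ## mid zone moves in anti-phase). The bladder interior (urine) and the
  ## region around its walls are anechoic, so no scatterers lie there.
  scatterers <- with_seed(seed + 1L, {
    z <- sort(runif(110, 3, 55))
    data.frame(depth_mm = z,
               amp = runif(110, 0.02, 0.1),
               mode = ifelse(z < 33, "resp", "anti"),
               stringsAsFactors = FALSE)
  })

  structure(list(config = config, trajectory = traj, organ_geometry = geom,
                 reflectors = reflectors, scatterers = scatterers,
                 seed = as.integer(seed)),
            class = "motion_phantom")
}

#' @export
print.motion_phantom <- function(x, ...) {
  cat("<motion_phantom>", x$config$region, "\n")
  cat(sprintf("  grid %dx%d, pixel %.2f mm, duration %.1f s\n",
              x$config$grid_shape[1], x$config$grid_shape[2],
              x$config$pixel_size_mm, x$config$duration_s))
  cat(sprintf("  resp amplitude %.1f mm p-p, period %.1f s\n",
              x$config$resp_amplitude_mm, x$config$breath_period_s))
  tab <- table(x$trajectory$event_labels)
  cat("  events:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

## trajectory values at arbitrary times
traj_at <- function(phantom, what, t) {
  tr <- phantom$trajectory
  interp_curve(tr$times, tr[[what]], t)
}

## event label at arbitrary times (nearest sample)
label_at <- function(phantom, t) {
  tr <- phantom$trajectory
  idx <- pmin(pmax(round(t * phantom$config$sample_rate_hz) + 1L, 1L),
              length(tr$times))
  tr$event_labels[idx]
}
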