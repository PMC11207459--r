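#' Default run configuration
#'
#' The full configuration tree driving [run_pipeline()]: a seed, the
#' simulator blocks (phantom, sequence, ultrasound, camera, SDR) and the
#' per-pipeline processing blocks with the acquisition-protocol defaults
#' (20 mm gating threshold, 5120-sample SDR blocks, 9th-order median
#' filter, 0-33 / 33-66 mm depth bands, ...).
#'
#' @return nested named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 42L,
    phantom = list(region = "abdomen", duration_s = 30,
                   resp_amplitude_mm = 10, breath_period_s = 4),
    sequence = list(n_spokes = 402L, pt_offset_hz = 48e3),
    ultrasound = list(prf_hz = 100),
    camera = list(frame_rate_hz = 5),
    sdr = list(fs_hz = 3e5, block = 512L, noise_sd = 0.01),
    pt = list(gate_threshold_mm = 20, pt_gain = 0.4, pt_noise_sd = 0.02,
              unet = list(epochs = 30L, base_width = 4L),
              fcn = list(epochs = 300L, window = 16L)),
    ocm = list(depth_bands_mm = list(c(0, 33), c(33, 66)),
               cnn = list(epochs = 400L, patience = 40L)),
    tof = list(),
    fusion = list(rate_hz = 20),
    out_dir = "."
  ), class = "run_config")
}

## recursively check for keys absent from the reference tree
unknown_keys <- function(cfg, ref, prefix = "") {
  bad <- character(0)
  for (nm in names(cfg)) {
    if (!nm %in% names(ref)) {
      bad <- c(bad, paste0(prefix, nm))
    } else if (is.list(cfg[[nm]]) && is.list(ref[[nm]]) &&
               !is.null(names(ref[[nm]]))) {
      bad <- c(bad, unknown_keys(cfg[[nm]], ref[[nm]],
                                 paste0(prefix, nm, ".")))
    }
  }
  bad
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; known keys override [default_run_config()]
#' and the result round-trips losslessly through YAML.
#'
#' @param path YAML file.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ref <- default_run_config()
  bad <- unknown_keys(cfg, ref)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  out <- modifyList(ref, cfg)
  class(out) <- "run_config"
  out
}

#' Write a run configuration to YAML
#'
#' @param config a `run_config`.
#' @param path output file.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
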