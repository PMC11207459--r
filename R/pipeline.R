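## End-to-end pipeline stages over the run container. Each stage reads
## its upstream artifacts from `config$out_dir`, writes its outputs
## there, and appends a structured JSON log entry (config hash, seed,
## package version, QC flags).

stage_paths <- function(config) {
  d <- config$out_dir
  list(run = file.path(d, "run.rds"),
       model_pt = file.path(d, "model_pt.rds"),
       model_pt_json = file.path(d, "model_pt.json"),
       model_ocm = file.path(d, "model_ocm.rds"),
       model_ocm_json = file.path(d, "model_ocm.json"),
       recon_ungated = file.path(d, "recon_ungated.nii.gz"),
       recon_gated = file.path(d, "recon_gated.nii.gz"),
       tof_csv = file.path(d, "tof_waveform.csv"),
       area_csv = file.path(d, "bladder_area.csv"),
       bundle_csv = file.path(d, "bundle.csv"),
       events_json = file.path(d, "events.json"),
       log = file.path(d, "pipeline_log.json"))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

append_log <- function(config, stage, extra = list()) {
  p <- stage_paths(config)$log
  entry <- c(list(stage = stage, time = format(Sys.time()),
                  seed = config$seed, config_hash = config_hash(config),
                  package_version = as.character(
                    utils::packageVersion("mrmotion"))),
             extra)
  log <- if (file.exists(p)) jsonlite::read_json(p) else list()
  log[[length(log) + 1L]] <- entry
  jsonlite::write_json(log, p, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(entry)
}

need_artifact <- function(path, produced_by) {
  if (!file.exists(path))
    stop(sprintf("dependency error: missing %s; run stage '%s' first",
                 basename(path), produced_by), call. = FALSE)
  path
}

#' Save / load a trained model with a JSON header
#'
#' The weights go to an R serialization file; a JSON sidecar records the
#' architecture, normalisation statistics and training metadata.
#'
#' @param model a `unet_model`, `motion_model`, `area_model`, or the
#'   list bundles produced by the pipeline stages.
#' @param path `.rds` path; the JSON header is written alongside.
#' @return `path` (for `save_model`); the model (for `load_model`).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  hdr <- list(class = class(model)[1],
              fields = names(model),
              hyper = model$hyper, stats = model$stats,
              seed = model$seed)
  jsonlite::write_json(hdr, sub("\\.rds$", ".json", path),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

#' Run one pipeline stage
#'
#' Stages: `simulate` (generate phantom + all raw sensor streams into
#' the run container), `pt-calibrate` (train liver segmenter and
#' Pilot-Tone motion model), `pt-correct` (extract PT, predict
#' displacement, gate, reconstruct), `ocm-train` (bladder area ground
#' truth + 1D CNN), `tof-extract` (respiratory waveform),
#' `fusion-run` (simultaneous-sensor alignment and correlation).
#'
#' @param config a `run_config` (see [default_run_config()]).
#' @param stage stage name.
#' @return named list of artifact paths and stage metrics, invisibly.
#' @export
run_pipeline <- function(config = default_run_config(),
                         stage = c("simulate", "pt-calibrate", "pt-correct",
                                   "ocm-train", "tof-extract", "fusion-run")) {
  stage <- match.arg(stage)
  p <- stage_paths(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)

  if (stage == "simulate") {
    ph_cfg <- phantom_config(region = config$phantom$region,
                             duration_s = config$phantom$duration_s,
                             resp_amplitude_mm = config$phantom$resp_amplitude_mm,
                             breath_period_s = config$phantom$breath_period_s)
    phantom <- make_breathing_phantom(ph_cfg, seed = seed)
    calib <- render_image_series(phantom, seq_params())
    seqr <- seq_params_radial(n_spokes = config$sequence$n_spokes,
                              pt_offset_hz = config$sequence$pt_offset_hz)
    ks <- simulate_radial_kspace(phantom, seqr, seed = seed + 1L)
    resp <- list(timestamps = phantom$trajectory$times,
                 value = phantom$trajectory$resp_displacement)
    ks <- inject_pilot_tone(ks, resp, gain = config$pt$pt_gain,
                            noise_sd = config$pt$pt_noise_sd,
                            seed = seed + 2L)
    am <- simulate_amode(phantom, us_params(prf_hz = config$ultrasound$prf_hz),
                         seed = seed + 3L)
    tof <- simulate_tof_frames(phantom,
                               tof_params(frame_rate_hz = config$camera$frame_rate_hz),
                               seed = seed + 4L)
    iq <- simulate_sdr_stream(resp, f_pt_hz = 20e3,
                              fs_hz = config$sdr$fs_hz,
                              noise_sd = config$sdr$noise_sd,
                              seed = seed + 5L)
    ## pelvic companion run for the bladder pipeline
    ph_pel <- make_breathing_phantom(
      phantom_config(region = "pelvis",
                     duration_s = config$phantom$duration_s),
      seed = seed + 10L)
    calib_pel <- render_image_series(ph_pel, seq_params())
    am_pel <- simulate_amode(ph_pel,
                             us_params(prf_hz = config$ultrasound$prf_hz),
                             seed = seed + 11L)
    write_container(p$run, list(
      kspace = list(lines = ks$lines, timestamps = ks$timestamps,
                    angles = ks$angles, seq = ks$seq),
      amode = list(rf = am$rf, fs_hz = am$fs_hz, series = am,
                   pelvis = am_pel),
      tof = list(frames = tof$frames, validity = tof$validity,
                 timestamps = tof$timestamps, series = tof),
      iq = list(samples = iq$samples, fs_hz = iq$fs_hz, stream = iq),
      truth = list(phantom = phantom, pelvis_phantom = ph_pel,
                   calib = calib, calib_pelvis = calib_pel)))
    append_log(config, stage, list(artifacts = "run.rds"))
    return(invisible(list(run = p$run)))
  }

  groups <- read_container(need_artifact(p$run, "simulate"))

  if (stage == "pt-calibrate") {
    calib <- groups$truth$calib
    un <- config$pt$unet
    seg <- train_liver_segmenter(calib$frames, calib$masks,
                                 hyper = unet_hyper(epochs = un$epochs,
                                                    base_width = un$base_width),
                                 seed = seed + 20L)
    pred_masks <- predict_liver_masks(seg, calib$frames)
    disp <- extract_boundary_displacement(pred_masks, calib$pixel_size_mm,
                                          calib$timestamps)
    ks <- new_kspace_series(groups$kspace$lines, groups$kspace$angles,
                            groups$kspace$timestamps, groups$kspace$seq)
    pt <- extract_pt_signal(ks)
    fc <- config$pt$fcn
    mm <- train_motion_model(pt, disp,
                             hyper = fcn_hyper(epochs = fc$epochs,
                                               window = fc$window),
                             seed = seed + 21L)
    save_model(list(segmenter = seg, motion = mm, hyper = mm$hyper,
                    stats = mm$stats, seed = mm$seed), p$model_pt)
    append_log(config, stage,
               list(test_mse_norm = mm$test_mse_norm,
                    test_rmse_mm = mm$test_rmse_mm))
    return(invisible(list(model = p$model_pt, motion = mm)))
  }

  if (stage == "pt-correct") {
    model <- load_model(need_artifact(p$model_pt, "pt-calibrate"))
    ks <- new_kspace_series(groups$kspace$lines, groups$kspace$angles,
                            groups$kspace$timestamps, groups$kspace$seq)
    pt <- extract_pt_signal(ks)
    disp <- predict_displacement(model$motion, pt)
    recon0 <- reconstruct_nufft(ks)
    gated <- gate_kspace(ks, disp,
                         threshold_mm = config$pt$gate_threshold_mm)
    recon1 <- reconstruct_nufft(gated)
    RNifti::writeNifti(RNifti::asNifti(recon0), p$recon_ungated)
    RNifti::writeNifti(RNifti::asNifti(recon1), p$recon_gated)
    append_log(config, stage,
               list(retained_fraction = attr(gated, "retained_fraction")))
    return(invisible(list(ungated = p$recon_ungated, gated = p$recon_gated)))
  }

  if (stage == "ocm-train") {
    calib <- groups$truth$calib_pelvis
    if (is.null(calib))
      stop("dependency error: container lacks the pelvic run; re-run 'simulate'",
           call. = FALSE)
    area <- segment_bladder_area(calib)
    am <- reconstruct_amode(groups$amode$pelvis)
    cn <- config$ocm$cnn
    model <- train_area_predictor(am, area,
                                  hyper = cnn_hyper(epochs = cn$epochs,
                                                    patience = cn$patience),
                                  seed = seed + 30L)
    save_model(model, p$model_ocm)
    pred <- predict_area(model, am)
    write_curve_csv(pred, p$area_csv)
    append_log(config, stage, list(test_mae_mm2 = model$test_mae_mm2))
    return(invisible(list(model = p$model_ocm, mae = model$test_mae_mm2)))
  }

  if (stage == "tof-extract") {
    wf <- extract_respiratory_waveform(groups$tof$series)
    write_curve_csv(wf, p$tof_csv)
    append_log(config, stage,
               list(n_missing = length(attr(wf, "qc")$missing_frames)))
    return(invisible(list(waveform = p$tof_csv)))
  }

  ## fusion-run
  am <- reconstruct_amode(groups$amode$series)
  bands <- config$ocm$depth_bands_mm
  curves <- list(
    pt = demodulate_sdr(groups$iq$stream, block = config$sdr$block),
    ocm_band1 = ocm_band_displacement(am, bands[[1]]),
    ocm_band2 = ocm_band_displacement(am, bands[[2]]),
    tof = extract_respiratory_waveform(groups$tof$series))
  bundle <- align_streams(curves, rate_hz = config$fusion$rate_hz)
  rep <- correlate_sensors(bundle)
  write.csv(data.frame(time = bundle$timeline, bundle$curves),
            p$bundle_csv, row.names = FALSE)
  jsonlite::write_json(rep$events, p$events_json, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  append_log(config, stage,
             list(correlation = as.list(stats::setNames(
               rep$correlation[upper.tri(rep$correlation)],
               c("pt.ocm1", "pt.ocm2", "ocm1.ocm2",
                 "pt.tof", "ocm1.tof", "ocm2.tof")))))
  invisible(list(bundle = p$bundle_csv, correlation = rep$correlation,
                 events = rep$events))
}
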