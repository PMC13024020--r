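#' Pipeline configuration
#'
#' Assembles and validates the end-to-end configuration. Defaults equal
#' the acquisition and processing parameters of the measurement setup:
#' 80 MHz RF sampling, 200 Hz frame rate, 2-8 MHz order-4 RF bandpass,
#' 6x interpolation (480 MHz), 0.4-16 Hz order-4 pulse bandpass,
#' 5-point Savitzky-Golay derivatives, top-20 feature grid, groups 1-2
#' as training split. The configuration round-trips losslessly through
#' YAML ([write_config()] / [read_config()]).
#'
#' @param ... overrides of any default field.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    n_subjects = 14,
    master_seed = 42,
    emit = "waveforms",
    duration_s = 12,
    fs_waveform = 200,
    fs_rf = 80e6,
    prf = 200,
    c_m_s = 1540,
    rf_band_hz = c(2e6, 8e6),
    rf_order = 4,
    interp_factor = 6,
    roi_half_width = 40,
    delta_range = c(-40, 40),
    subsample = TRUE,
    pulse_band_hz = c(0.4, 16),
    pulse_order = 4,
    sg_window = 5,
    sg_order = 2,
    max_features = 20,
    cv_folds = 5,
    methods = c("mlr", "rf", "xgb"),
    train_groups = c(1, 2))
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop_arg("unknown config field(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, over)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config a `"pipeline_config"`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the end-to-end pipeline
#'
#' Chains the stages on synthetic data: cohort and dataset generation
#' (optionally through RF synthesis and echo tracking), feature
#' extraction, and the per-subject calibration study. Artifacts
#' (feature table CSV, report JSON) are written to `out_dir` when given,
#' stamped with the master seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for artifacts.
#' @return The `"bp_study"` report, with attributes `features`
#'   (the feature table) and `dataset`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- make_cohort(config$n_subjects, config$master_seed)
  ds <- generate_dataset(cohort, master_seed = config$master_seed,
                         duration = config$duration_s,
                         fs = config$fs_waveform, emit = "waveforms")
  if (config$emit == "rf") {
    # re-derive each waveform through RF synthesis + echo tracking
    for (rid in names(ds$waveforms)) {
      sid <- ds$records$subject_id[ds$records$record_id == rid]
      prof <- ds$cohort[[which(vapply(ds$cohort, `[[`, "", "subject_id")
                               == sid)]]
      es <- synthesize_echo_frames(
        ds$waveforms[[rid]], prof,
        rf_config = list(fs_rf = config$fs_rf, c = config$c_m_s),
        seed = config$master_seed)
      tr <- track_distension(
        es, band = config$rf_band_hz, order = config$rf_order,
        interp_factor = config$interp_factor,
        half_width = config$roi_half_width, delta = config$delta_range,
        subsample = config$subsample)
      tr$dd <- tr$dd - mean(tr$dd)
      ds$waveforms[[rid]] <- tr
    }
  }
  feats <- build_feature_table(ds)
  study <- run_study(feats, methods = config$methods,
                     max_features = config$max_features,
                     cv_folds = config$cv_folds,
                     seed = config$master_seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_csv(feats, file.path(out_dir, sprintf(
      "features_seed%d.csv", config$master_seed)))
    write_report_json(study, file.path(out_dir, sprintf(
      "report_seed%d.json", config$master_seed)))
    write_config(config, file.path(out_dir, "config.yaml"))
  }
  attr(study, "features") <- feats
  attr(study, "dataset") <- ds
  study
}
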