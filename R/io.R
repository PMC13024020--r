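# Readers/writers for the pipeline's on-disk formats. All text formats
# are UTF-8 CSV/JSON; the echo container is raw little-endian int16 with
# a JSON sidecar carrying the acquisition metadata.

#' Write / read a distension waveform CSV
#'
#' Columns `t_s`, `dd_um`; the sampling rate is recovered from the time
#' column on read.
#'
#' @param dd a `"distension_waveform"`.
#' @param path output path.
#' @return `read_waveform_csv()` returns a `"distension_waveform"`.
#' @export
write_waveform_csv <- function(dd, path) {
  stopifnot(inherits(dd, "distension_waveform"))
  utils::write.csv(
    data.frame(t_s = (seq_along(dd$dd) - 1) / dd$fs, dd_um = dd$dd),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("t_s", "dd_um") %in% names(df)))
    stop_arg("waveform CSV %s: expected columns t_s, dd_um", path)
  fs <- 1 / stats::median(diff(df$t_s))
  structure(list(dd = df$dd_um, fs = round(fs), provenance = "tracked",
                 annotations = NULL),
            class = "distension_waveform")
}

#' Write / read an RF echo container
#'
#' Raw little-endian int16 samples (frame-major) plus a JSON sidecar
#' (`<path>.json`) carrying `fs_rf`, `prf`, `c`, `z0_mm`, `n_frames`,
#' `n_samples` and the int16 `scale` used for quantization.
#'
#' @param seq an [echo_sequence()].
#' @param path output path for the binary payload.
#' @return `read_echo_bin()` returns an [echo_sequence()] (amplitudes in
#'   original units, up to int16 quantization).
#' @export
write_echo_bin <- function(seq, path) {
  stopifnot(inherits(seq, "echo_sequence"))
  peak <- max(abs(seq$rf), 1e-12)
  scale <- 32000 / peak
  q <- as.integer(round(t(seq$rf) * scale))  # frame-major on disk
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(q, con, size = 2, endian = "little")
  jsonlite::write_json(
    list(fs_rf = seq$fs_rf, prf = seq$prf, c = seq$c, z0_mm = seq$z0_mm,
         n_frames = nrow(seq$rf), n_samples = ncol(seq$rf),
         scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_echo_bin
#' @export
read_echo_bin <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  need <- c("fs_rf", "prf", "c", "z0_mm", "n_frames", "n_samples", "scale")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop_arg("echo sidecar %s.json: missing field(s) %s", path,
             paste(miss, collapse = ", "))
  con <- file(path, "rb")
  on.exit(close(con))
  q <- readBin(con, "integer", n = meta$n_frames * meta$n_samples,
               size = 2, endian = "little")
  rf <- t(matrix(q / meta$scale, meta$n_samples, meta$n_frames))
  echo_sequence(rf, fs_rf = meta$fs_rf, prf = meta$prf, c = meta$c,
                z0_mm = meta$z0_mm)
}

#' Write / read per-beat fiducial annotations as JSON
#'
#' @param beats list of `"beat_annotation"` objects.
#' @param path output path.
#' @return `read_beats_json()` returns the list of annotations.
#' @export
write_beats_json <- function(beats, path) {
  ser <- lapply(beats, function(b) {
    b$quality_flags <- as.list(b$quality_flags)
    unclass(b)
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_beats_json
#' @export
read_beats_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(b) {
    b <- lapply(b, function(v) if (is.null(v)) NA else v)
    b$quality_flags <- as.character(unlist(b$quality_flags))
    int_fields <- setdiff(names(b), c("fs", "quality_flags"))
    b[int_fields] <- lapply(b[int_fields], function(v)
      if (is.na(v)) NA_integer_ else as.integer(v))
    structure(b, class = "beat_annotation")
  })
}

#' Write / read the record-level feature table CSV
#'
#' One row per record: metadata columns then the 52 canonical features.
#' Absent values are empty cells. Reading validates the column set and
#' names any unknown column in the error.
#'
#' @param df feature table (see [build_feature_table()]).
#' @param path output path.
#' @return `read_feature_csv()` returns the data frame.
#' @export
write_feature_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta_cols <- c("subject_id", "record_id", "group", "split", "phase",
                 "sbp_mmhg", "hr_bpm")
  known <- c(meta_cols, feature_registry()$name)
  unknown <- setdiff(names(df), known)
  if (length(unknown))
    stop_arg("feature CSV %s: unknown column(s): %s", path,
             paste(unknown, collapse = ", "))
  df
}

#' Write a study report as JSON
#'
#' Per-subject configurations and metrics, pooled metrics and composite
#' rankings of a [run_study()] result.
#'
#' @param study a `"bp_study"`.
#' @param path output path.
#' @export
write_report_json <- function(study, path) {
  stopifnot(inherits(study, "bp_study"))
  ser <- list(
    seed = study$seed,
    pooled = study$pooled,
    subjects = lapply(study$subjects, function(s) list(
      subject_id = s$subject_id,
      method = s$config$method, n_features = s$config$n_features,
      features = s$config$features, cv_mae = s$config$cv_mae,
      short = s$eval_short[c("mae", "sd_abs_err", "pearson_r", "n")],
      long = if (!is.null(s$eval_long))
        s$eval_long[c("mae", "sd_abs_err", "pearson_r", "n")] else NULL,
      mvm_short = s$mvm_short[c("mae", "sd_abs_err", "pearson_r", "n")],
      mvm_long = if (!is.null(s$mvm_long))
        s$mvm_long[c("mae", "sd_abs_err", "pearson_r", "n")] else NULL)),
    composite = study$composite)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
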