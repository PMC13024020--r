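#' Generate the full synthetic study dataset
#'
#' Runs the acquisition protocol for every subject across session groups
#' 1-4: SBP/HR trajectories per session, one 12 s distension segment per
#' record whose morphology is driven by the record's latent SBP. Groups
#' 1-2 form the training split, group 3 the short-term test split, group
#' 4 the long-term split; for group 4 the subject's morphology
#' coefficients receive a small seeded drift, emulating the physiological
#' changes that degrade calibration after days.
#'
#' @param cohort a [make_cohort()] cohort.
#' @param master_seed integer; all per-session and per-record seeds derive
#'   from it.
#' @param groups which session groups to simulate. Default 1:4.
#' @param duration,fs record length (s) and waveform rate (Hz).
#' @param drift_sd relative SD of the group-4 morphology drift. Default
#'   0.02.
#' @param emit `"waveforms"` (default) or `"rf"`: whether records carry
#'   the distension waveform or raw echo frames (echo synthesis is much
#'   heavier; used for round-trip validation).
#' @param rf_config passed to [synthesize_echo_frames()] when
#'   `emit = "rf"`.
#' @return A list of class `"synth_dataset"`: `records` (data frame with
#'   subject_id, record_id, group, split, phase, record_time_s, sbp_mmhg
#'   label, hr_bpm, sbp_true), `waveforms` or `echoes` (lists indexed by
#'   record_id), and `cohort`.
#' @export
generate_dataset <- function(cohort = make_cohort(), master_seed = 42,
                             groups = 1:4, duration = 12, fs = 200,
                             drift_sd = 0.02,
                             emit = c("waveforms", "rf"),
                             rf_config = list()) {
  emit <- match.arg(emit)
  if (!all(groups %in% 1:4)) stop_arg("groups must be a subset of 1:4")
  recs <- list(); waves <- list(); echoes <- list()
  for (si in seq_along(cohort)) {
    prof <- cohort[[si]]
    # group-4 morphology drift, seeded per subject
    prof4 <- prof
    set.seed(fanout_seed(master_seed, 9000 + si))
    mc <- prof4$morphology_coefficients
    for (nm in c("amp0", "rt0", "rd0", "rr0")) {
      mc[[nm]] <- mc[[nm]] * (1 + stats::rnorm(1, 0, drift_sd))
    }
    prof4$morphology_coefficients <- mc
    for (g in groups) {
      sched <- protocol_schedule(g)
      traj <- simulate_sbp_trajectory(
        prof, sched, seed = fanout_seed(master_seed, si * 10 + g))
      p_use <- if (g == 4) prof4 else prof
      for (r in seq_len(nrow(traj))) {
        rid <- sprintf("%s_g%d_r%02d", prof$subject_id, g, r)
        dw <- synthesize_distension_segment(
          p_use, traj$sbp_true[r], traj$hr_true[r], duration, fs,
          seed = fanout_seed(master_seed, si * 1000 + g * 100 + r))
        recs[[length(recs) + 1]] <- data.frame(
          subject_id = prof$subject_id, record_id = rid, group = g,
          split = c("train", "train", "short_term", "long_term")[g],
          phase = traj$phase[r], record_time_s = traj$record_time_s[r],
          sbp_mmhg = traj$sbp_mmhg[r], hr_bpm = traj$hr_bpm[r],
          sbp_true = traj$sbp_true[r], stringsAsFactors = FALSE)
        if (emit == "waveforms") waves[[rid]] <- dw
        else echoes[[rid]] <- synthesize_echo_frames(
          dw, p_use, rf_config,
          seed = fanout_seed(master_seed, si * 1000 + g * 100 + r + 1))
      }
    }
  }
  structure(list(records = do.call(rbind, recs),
                 waveforms = if (emit == "waveforms") waves else NULL,
                 echoes = if (emit == "rf") echoes else NULL,
                 cohort = cohort),
            class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf("<synth_dataset> %d subjects, %d records (%s)\n",
              length(x$cohort), nrow(x$records),
              if (is.null(x$echoes)) "waveforms" else "rf frames"))
  print(table(x$records$split))
  invisible(x)
}

#' Build the record-level feature table of a dataset
#'
#' Runs the feature pipeline on every record's distension waveform and
#' returns one row per record: metadata columns followed by the 52
#' canonical features. Records with fewer than three valid beats are
#' dropped (with a warning giving the count).
#'
#' @param dataset a `"synth_dataset"` carrying waveforms.
#' @param bandpass logical, apply the 0.4-16 Hz filter per record.
#' @return Data frame: `subject_id`, `record_id`, `group`, `split`,
#'   `phase`, `sbp_mmhg`, `hr_bpm`, then the 52 features.
#' @export
build_feature_table <- function(dataset, bandpass = TRUE) {
  stopifnot(inherits(dataset, "synth_dataset"),
            !is.null(dataset$waveforms))
  heights <- stats::setNames(
    vapply(dataset$cohort, function(p) p$height, numeric(1)),
    vapply(dataset$cohort, function(p) p$subject_id, character(1)))
  rows <- list(); dropped <- 0L
  for (r in seq_len(nrow(dataset$records))) {
    meta <- dataset$records[r, ]
    fv <- try(extract_record_features(
      dataset$waveforms[[meta$record_id]],
      height = heights[[meta$subject_id]], bandpass = bandpass),
      silent = TRUE)
    if (inherits(fv, "try-error")) { dropped <- dropped + 1L; next }
    rows[[length(rows) + 1]] <- cbind(
      meta[, c("subject_id", "record_id", "group", "split", "phase",
               "sbp_mmhg", "hr_bpm")],
      as.data.frame(as.list(fv)))
  }
  if (dropped > 0)
    warning(sprintf("%d record(s) dropped (fewer than 3 valid beats)",
                    dropped))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
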