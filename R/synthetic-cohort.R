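#' Simulate a cohort of subjects
#'
#' Draws per-subject physiology for the synthetic study: height, baseline
#' systolic pressure and heart rate, carotid wall depths, and the
#' morphology coefficients that couple SBP deviations to beat-template
#' parameters. The population is configured to a baseline SBP of
#' 125 mmHg (SD 10) in healthy young adults.
#'
#' @param n_subjects number of subjects (>= 1). Default 14.
#' @param master_seed integer master seed; all per-subject seeds are
#'   derived from it deterministically.
#' @param population list overriding population parameters: `sbp_mean`,
#'   `sbp_sd`, `hr_mean`, `hr_sd`, `noise_level` (relative RF noise).
#' @return A list of class `"subject_cohort"` of `"subject_profile"`
#'   objects. Each profile carries `subject_id`, `height` (m),
#'   `baseline_sbp` (mmHg), `baseline_hr` (bpm), `wall_depth_prox` /
#'   `wall_depth_dist` (mm), `morphology_coefficients`, `noise_level`
#'   and `seed`.
#' @export
make_cohort <- function(n_subjects = 14, master_seed = 7,
                        population = list()) {
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop_arg("n_subjects must be a positive count")
  n_subjects <- as.integer(n_subjects)
  pop <- utils::modifyList(
    list(sbp_mean = 125, sbp_sd = 10, hr_mean = 64, hr_sd = 7,
         noise_level = 0.1), population)
  seeds <- fanout_seed(master_seed, seq_len(n_subjects))
  cohort <- lapply(seq_len(n_subjects), function(i) {
    set.seed(seeds[i])
    sbp <- stats::rnorm(1, pop$sbp_mean, pop$sbp_sd)
    sbp <- min(max(sbp, 90), 160)
    hr <- min(max(stats::rnorm(1, pop$hr_mean, pop$hr_sd), 48), 90)
    prox <- stats::rnorm(1, 15, 1)
    lumen <- max(stats::rnorm(1, 7, 0.7), 4.5)
    # subject-level variation around the canonical template and the
    # SBP-coupling slopes (per-mmHg fractional changes)
    mc <- list(
      amp0 = 420 * (1 + stats::rnorm(1, 0, 0.07)),
      rt0 = 0.13 * (1 + stats::rnorm(1, 0, 0.05)),
      rd0 = 0.12 * (1 + stats::rnorm(1, 0, 0.05)),
      rr0 = 0.45 * (1 + stats::rnorm(1, 0, 0.08)),
      depth0 = 0.15 * (1 + stats::rnorm(1, 0, 0.08)),
      c_amp = 0.004 * (1 + stats::rnorm(1, 0, 0.15)),
      c_rt = 0.004 * (1 + stats::rnorm(1, 0, 0.15)),
      c_rd = 0.005 * (1 + stats::rnorm(1, 0, 0.15)),
      c_rr = 0.006 * (1 + stats::rnorm(1, 0, 0.15)))
    p <- list(subject_id = sprintf("S%02d", i),
              height = stats::runif(1, 1.55, 1.95),
              baseline_sbp = sbp, baseline_hr = hr,
              wall_depth_prox = prox, wall_depth_dist = prox + lumen,
              morphology_coefficients = mc,
              noise_level = pop$noise_level,
              seed = seeds[i])
    class(p) <- "subject_profile"
    p
  })
  class(cohort) <- "subject_cohort"
  cohort
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf(
    "<subject_profile %s>  height %.2f m, baseline SBP %.1f mmHg, HR %.0f bpm\n",
    x$subject_id, x$height, x$baseline_sbp, x$baseline_hr))
  cat(sprintf("  walls at %.1f / %.1f mm, noise level %.2f\n",
              x$wall_depth_prox, x$wall_depth_dist, x$noise_level))
  invisible(x)
}

#' Acquisition schedule for one experimental session
#'
#' Returns the phase structure of one data-collection session: rest, cold
#' pressor (two immersions with a short recovery), recovery after the cold
#' pressor, and the recovery period after cycling exercise. Record counts
#' per phase are fixed so that the two training sessions together yield
#' about 39 records, the short-term test session about 19, and the
#' long-term follow-up about 24.
#'
#' @param group_id session group, 1-4. Groups 1-2 are training sessions,
#'   group 3 the same-day test session, group 4 a follow-up at least two
#'   days later.
#' @return A list of class `"protocol_schedule"` with `phases` (data frame
#'   of `phase_label`, `duration_s`, `target_records`), `group_id` and
#'   `session_gap_days`.
#' @export
protocol_schedule <- function(group_id) {
  if (!group_id %in% 1:4) stop_arg("group_id must be 1, 2, 3 or 4")
  counts <- switch(as.character(group_id),
                   "1" = c(3, 9, 2, 6),
                   "2" = c(3, 9, 2, 6),
                   "3" = c(2, 9, 2, 6),
                   "4" = c(3, 11, 3, 7))
  phases <- data.frame(
    phase_label = c("rest", "cold_pressor", "cp_recovery", "post_exercise"),
    duration_s = c(120, 180, 90, 300),
    target_records = counts,
    stringsAsFactors = FALSE)
  structure(list(phases = phases, group_id = group_id,
                 session_gap_days = if (group_id == 4) 7 else 0),
            class = "protocol_schedule")
}

#' Simulate an SBP/heart-rate trajectory over one session
#'
#' Produces one (time, phase, SBP, HR) row per acquisition record following
#' the session protocol. The cold pressor raises SBP by a ramp to a
#' subject-level peak of at least ~15 mmHg; the post-exercise phase starts
#' near its peak elevation and decays monotonically back toward baseline;
#' heart rate is elevated after exercise. Record-level measurement noise
#' emulates the reference device.
#'
#' @param profile a `"subject_profile"`.
#' @param schedule a [protocol_schedule()] object.
#' @param seed integer seed for this session.
#' @param effects list overriding effect magnitudes: `cp_peak_range`,
#'   `ex_peak_range` (mmHg, uniform draws), `noise_sd` (mmHg),
#'   `hr_ex_peak`, `hr_cp` (bpm).
#' @return Data frame with columns `record_time_s`, `phase`, `sbp_mmhg`,
#'   `hr_bpm`.
#' @export
simulate_sbp_trajectory <- function(profile, schedule, seed,
                                    effects = list()) {
  if (!inherits(schedule, "protocol_schedule") ||
      nrow(schedule$phases) == 0)
    stop_arg("schedule must be a non-empty protocol_schedule")
  eff <- utils::modifyList(
    list(cp_peak_range = c(17, 23), ex_peak_range = c(26, 32),
         noise_sd = 2, hr_ex_peak = 28, hr_cp = 6), effects)
  set.seed(seed)
  cp_peak <- stats::runif(1, eff$cp_peak_range[1], eff$cp_peak_range[2])
  ex_peak <- stats::runif(1, eff$ex_peak_range[1], eff$ex_peak_range[2])

  t0 <- 0
  rows <- lapply(seq_len(nrow(schedule$phases)), function(i) {
    ph <- schedule$phases[i, ]
    n <- ph$target_records
    tt <- t0 + ph$duration_s * (seq_len(n) - 0.5) / n
    rise <- switch(ph$phase_label,
      rest = rep(0, n),
      cold_pressor = cp_peak * seq(0.4, 1, length.out = n),
      cp_recovery = cp_peak * seq(0.5, 0.2, length.out = n),
      post_exercise = ex_peak * exp(-1.8 * (seq_len(n) - 0.5) / n))
    hr_rise <- switch(ph$phase_label,
      rest = rep(0, n),
      cold_pressor = rep(eff$hr_cp, n),
      cp_recovery = rep(eff$hr_cp / 2, n),
      post_exercise = eff$hr_ex_peak * exp(-1.8 * (seq_len(n) - 0.5) / n))
    t0 <<- t0 + ph$duration_s
    data.frame(record_time_s = tt, phase = ph$phase_label,
               sbp_true = profile$baseline_sbp + rise,
               hr_true = profile$baseline_hr + hr_rise,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$sbp_mmhg <- out$sbp_true + stats::rnorm(nrow(out), 0, eff$noise_sd)
  out$hr_bpm <- pmax(out$hr_true + stats::rnorm(nrow(out), 0, 1.5), 40)
  out[, c("record_time_s", "phase", "sbp_mmhg", "hr_bpm",
          "sbp_true", "hr_true")]
}
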