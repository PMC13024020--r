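#' Beat-template parameters implied by an SBP level
#'
#' Maps a subject's SBP deviation from baseline to the analytic beat
#' parameters through the subject's morphology coefficients: higher SBP
#' shortens the systolic rise, shortens the reflected-wave delay, and
#' increases the reflected-wave amplitude and the pulse amplitude, matching
#' the qualitative physiology of pressure-dependent waveform morphology.
#'
#' @param profile a `"subject_profile"`.
#' @param sbp SBP driving the morphology, mmHg.
#' @param hr heart rate, bpm (sets the cycle period).
#' @return A [beat_template_params()] object.
#' @export
morphology_params <- function(profile, sbp, hr) {
  mc <- profile$morphology_coefficients
  d <- sbp - profile$baseline_sbp
  T <- 60 / hr
  kap <- sqrt(T)
  beat_template_params(
    period_T = T,
    systolic_rise_time = mc$rt0 * kap * max(1 - mc$c_rt * d, 0.5),
    reflection_delay = mc$rd0 * kap * max(1 - mc$c_rd * d, 0.5),
    reflection_amplitude_ratio = mc$rr0 * max(1 + mc$c_rr * d, 0.05),
    dicrotic_depth = mc$depth0,
    amplitude = mc$amp0 * max(1 + mc$c_amp * d, 0.2))
}

#' Synthesize a distension-waveform segment with ground truth
#'
#' Concatenates analytic beats whose template parameters are a
#' deterministic function of the SBP deviation from the subject's
#' baseline, plus seeded beat-to-beat jitter, and records the true
#' fiducial times of every beat. This is the recoverable ground truth
#' against which beat segmentation, fiducial detection and feature
#' extraction are validated.
#'
#' @param profile a `"subject_profile"`.
#' @param sbp SBP driving the morphology, mmHg.
#' @param hr heart rate, bpm.
#' @param duration segment length in seconds (>= 2 beats). Default 12 s.
#' @param fs sampling rate, Hz (>= 100). Default 200.
#' @param seed integer seed for the beat-to-beat jitter.
#' @param jitter relative SD of beat-to-beat variation in period and
#'   amplitude; 0 disables it.
#' @return A list of class `"distension_waveform"`: `dd` (micrometres),
#'   `fs`, `provenance = "synthetic"`, and `annotations` - a data frame
#'   with one row per complete beat (`onset_t`, `peak_t`, `notch_t`,
#'   `dias_t` in seconds from segment start; `onset_i` 1-based sample
#'   index; period, rise time and reflection parameters of the beat).
#' @export
synthesize_distension_segment <- function(profile, sbp, hr,
                                          duration = 12, fs = 200,
                                          seed = 1, jitter = 0.02) {
  if (fs < 100) stop_arg("fs must be >= 100 Hz")
  if (duration < 2 * 60 / hr) stop_arg("duration must cover >= 2 beats")
  set.seed(seed)
  n_total <- round(duration * fs)
  dd <- numeric(n_total)
  ann <- list()
  pos <- 0L  # samples filled so far
  while (pos < n_total) {
    hr_b <- hr * (1 + if (jitter > 0) stats::rnorm(1, 0, jitter) else 0)
    amp_j <- 1 + (if (jitter > 0) stats::rnorm(1, 0, jitter / 2) else 0)
    par <- morphology_params(profile, sbp, hr_b)
    par$amplitude <- par$amplitude * amp_j
    bt <- beat_template(par, fs)
    nb <- length(bt$samples)
    take <- min(nb, n_total - pos)
    dd[pos + seq_len(take)] <- bt$samples[seq_len(take)]
    if (take == nb) {  # complete beat: keep its ground truth
      t0 <- pos / fs
      ann[[length(ann) + 1]] <- data.frame(
        onset_t = t0, peak_t = t0 + bt$fiducials$peak,
        notch_t = t0 + (bt$fiducials$notch %||% NA_real_),
        dias_t = t0 + (bt$fiducials$dias_peak %||% NA_real_),
        onset_i = pos + 1L,
        period_T = par$period_T,
        systolic_rise_time = par$systolic_rise_time,
        reflection_delay = par$reflection_delay,
        reflection_amplitude_ratio = par$reflection_amplitude_ratio,
        amplitude = par$amplitude)
    }
    pos <- pos + take
  }
  structure(list(dd = dd, fs = fs, provenance = "synthetic",
                 annotations = do.call(rbind, ann)),
            class = "distension_waveform")
}

#' @export
print.distension_waveform <- function(x, ...) {
  cat(sprintf("<distension_waveform> %d samples @ %g Hz (%.1f s), %s\n",
              length(x$dd), x$fs, length(x$dd) / x$fs, x$provenance))
  if (!is.null(x$annotations))
    cat(sprintf("  %d annotated ground-truth beats\n", nrow(x$annotations)))
  invisible(x)
}
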