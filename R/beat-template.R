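#' Parameters of a single analytic distension beat
#'
#' Bundles and validates the parameters of the analytic beat model used by
#' the synthetic-data generator: a systolic Gaussian lobe, a delayed
#' reflected Gaussian lobe, and an exponentially decaying dicrotic
#' oscillation appended after the reflected wave. Every fiducial landmark
#' of the model (onset, systolic peak, dicrotic notch, diastolic peak) is
#' known by construction, which is what makes the generator usable as
#' ground truth for the detection code.
#'
#' @param period_T cardiac cycle duration in seconds.
#' @param systolic_rise_time time from onset to the systolic lobe centre, s.
#' @param reflection_delay delay of the reflected lobe after the systolic
#'   lobe centre, s.
#' @param reflection_amplitude_ratio amplitude of the reflected lobe
#'   relative to the systolic lobe (unitless, >= 0).
#' @param dicrotic_depth depth of the dicrotic oscillation relative to the
#'   systolic lobe (unitless, >= 0).
#' @param amplitude peak distension amplitude in micrometres.
#' @return A list of class `"beat_template_params"`.
#' @export
beat_template_params <- function(period_T = 1.0,
                                 systolic_rise_time = 0.13,
                                 reflection_delay = 0.12,
                                 reflection_amplitude_ratio = 0.45,
                                 dicrotic_depth = 0.15,
                                 amplitude = 420) {
  p <- list(period_T = period_T,
            systolic_rise_time = systolic_rise_time,
            reflection_delay = reflection_delay,
            reflection_amplitude_ratio = reflection_amplitude_ratio,
            dicrotic_depth = dicrotic_depth,
            amplitude = amplitude)
  if (!(period_T > 0)) stop_arg("period_T must be positive")
  if (!(systolic_rise_time > 0 && systolic_rise_time < period_T))
    stop_arg("systolic_rise_time must lie in (0, period_T)")
  if (!(reflection_delay > 0 && reflection_delay < period_T))
    stop_arg("reflection_delay must lie in (0, period_T)")
  if (reflection_amplitude_ratio < 0)
    stop_arg("reflection_amplitude_ratio must be >= 0")
  if (dicrotic_depth < 0) stop_arg("dicrotic_depth must be >= 0")
  if (!(amplitude > 0)) stop_arg("amplitude must be positive")
  class(p) <- "beat_template_params"
  p
}

# Continuous (unnormalized) beat shape evaluated at times t.
# Shape constants scale with sqrt(T) so fast beats compress systole the way
# real cardiac cycles do.
beat_shape_eval <- function(t, p) {
  kap <- sqrt(p$period_T)
  sig_s <- p$systolic_rise_time / 3.5
  t_r <- p$systolic_rise_time + p$reflection_delay
  sig_r <- 2 * sig_s  # reflected waves arrive dispersed
  t_n <- t_r + 1.2 * sig_r
  P_d <- 0.26 * kap
  tau <- 0.15 * kap
  y <- exp(-(t - p$systolic_rise_time)^2 / (2 * sig_s^2)) +
    p$reflection_amplitude_ratio * exp(-(t - t_r)^2 / (2 * sig_r^2))
  u <- t - t_n
  on <- u > 0
  y[on] <- y[on] - p$dicrotic_depth * exp(-u[on] / tau) *
    sin(2 * pi * u[on] / P_d)
  # small pre-systolic foot dip: makes the cycle onset a strict waveform
  # minimum (as in measured distension pulses) while keeping |y(0)| < 1%
  pre <- t >= 0
  y[pre] <- y[pre] - 0.008 * exp(-t[pre] / (0.025 * kap))
  attr(y, "shape") <- list(sigma_s = sig_s, t_r = t_r, sigma_r = sig_r,
                           t_n = t_n, P_d = P_d, tau = tau)
  y
}

#' Sample one analytic distension beat
#'
#' Evaluates the analytic beat model on a uniform grid and locates its
#' fiducial landmarks on a dense auxiliary grid so they are exact to well
#' below one output sample.
#'
#' @param params a [beat_template_params()] object.
#' @param fs output sampling rate in Hz (>= 100).
#' @param dense_fs internal grid used to locate analytic landmarks, Hz.
#' @return A list of class `"beat_template"` with elements `samples`
#'   (micrometres, length `round(period_T * fs)`), `t` (seconds), `fs`,
#'   `params`, `shape` (internal lobe constants) and `fiducials`: analytic
#'   times (s) of `onset`, `peak`, `notch` and `dias_peak` (`NA` when the
#'   landmark does not exist, e.g. no dicrotic component).
#' @export
beat_template <- function(params, fs, dense_fs = 4000) {
  if (!inherits(params, "beat_template_params"))
    params <- do.call(beat_template_params, params)
  if (fs < 100) stop_arg("fs must be >= 100 Hz to resolve fiducials")
  T <- params$period_T
  td <- seq(0, T, by = 1 / dense_fs)
  yd <- beat_shape_eval(td, params)
  shape <- attr(yd, "shape")
  m <- max(yd)
  scale <- params$amplitude / m
  peak_t <- td[which.max(yd)]

  notch_t <- NA_real_
  dias_t <- NA_real_
  if (params$dicrotic_depth > 0) {
    lo <- shape$t_n
    hi <- min(shape$t_n + shape$P_d / 2, T)
    win <- which(td >= lo & td <= hi)
    if (length(win) > 2) {
      mins <- local_minima(yd[win])
      if (length(mins)) notch_t <- td[win[mins[1]]]
    }
    if (!is.na(notch_t)) {
      after <- which(td > notch_t)
      maxs <- local_maxima(yd[after])
      if (length(maxs)) dias_t <- td[after[maxs[1]]]
    }
  }

  n <- round(T * fs)
  t <- (seq_len(n) - 1) / fs
  y <- as.numeric(beat_shape_eval(t, params)) * scale
  structure(list(samples = y, t = t, fs = fs, params = params,
                 shape = shape,
                 fiducials = list(onset = 0, peak = peak_t,
                                  notch = notch_t, dias_peak = dias_t)),
            class = "beat_template")
}
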