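#' A-mode RF echo frame sequence
#'
#' Container for a sequence of radio-frequency A-mode echo frames: one row
#' per emission (frame), one column per fast-time sample.
#'
#' @param rf numeric matrix, frames x samples.
#' @param fs_rf RF sampling rate, Hz. Default 80 MHz.
#' @param prf pulse repetition frequency (frame rate), Hz. Default 200.
#' @param c speed of sound, m/s. Default 1540.
#' @param z0_mm depth of the first fast-time sample, mm. Default 0.
#' @return A list of class `"echo_sequence"`.
#' @export
echo_sequence <- function(rf, fs_rf = 80e6, prf = 200, c = 1540,
                          z0_mm = 0) {
  if (!is.matrix(rf) || nrow(rf) < 2)
    stop_arg("rf must be a matrix with at least 2 frames")
  if (fs_rf <= 0 || prf <= 0) stop_arg("fs_rf and prf must be positive")
  structure(list(rf = rf, fs_rf = fs_rf, prf = prf, c = c, z0_mm = z0_mm),
            class = "echo_sequence")
}

#' @export
print.echo_sequence <- function(x, ...) {
  cat(sprintf(
    "<echo_sequence> %d frames x %d samples @ %.0f MHz, PRF %g Hz, c = %g m/s\n",
    nrow(x$rf), ncol(x$rf), x$fs_rf / 1e6, x$prf, x$c))
  cat(sprintf("  depth window %.1f - %.1f mm (%.3f mm/sample two-way)\n",
              x$z0_mm, x$z0_mm + (ncol(x$rf) - 1) * sample_span_mm(x),
              sample_span_mm(x)))
  invisible(x)
}

# two-way depth per fast-time sample, mm
sample_span_mm <- function(seq) seq$c / (2 * seq$fs_rf) * 1e3

#' Device geometry constants
#'
#' Two-way range arithmetic of the acquisition setup: the depth span of
#' an ROI window at the raw sampling rate, and the displacement quantum
#' (micrometres per sample) at the interpolated rate used by the
#' tracker.
#'
#' @param fs_rf RF sampling rate, Hz. Default 80 MHz.
#' @param c speed of sound, m/s. Default 1540.
#' @param roi_samples ROI window length in raw samples. Default 80.
#' @param interp_factor interpolation factor. Default 6.
#' @return List with `roi_span_mm` (depth covered by the ROI) and
#'   `displacement_quantum_um` (shift resolution of one interpolated
#'   sample).
#' @export
device_geometry <- function(fs_rf = 80e6, c = 1540, roi_samples = 80,
                            interp_factor = 6) {
  per_sample_mm <- c / (2 * fs_rf) * 1e3
  list(roi_span_mm = roi_samples * per_sample_mm,
       displacement_quantum_um = c / (2 * fs_rf * interp_factor) * 1e6)
}

#' Bandpass-filter every RF frame
#'
#' Applies a zero-phase Butterworth bandpass (default 2-8 MHz, 4th order)
#' to each frame independently. Zero-phase (forward-backward) filtering is
#' used so echo peak positions are not biased.
#'
#' @param seq an [echo_sequence()].
#' @param lo,hi band edges, Hz.
#' @param order filter order (even; realized as a Butterworth of this
#'   total order).
#' @return A filtered [echo_sequence()] of identical shape.
#' @export
bandpass_rf <- function(seq, lo = 2e6, hi = 8e6, order = 4) {
  stopifnot(inherits(seq, "echo_sequence"))
  if (!(lo > 0 && lo < hi && hi < seq$fs_rf / 2))
    stop_arg("band must satisfy 0 < lo < hi < fs_rf/2")
  if (order %% 2 != 0) stop_arg("order must be even")
  bf <- signal::butter(order / 2, c(lo, hi) / (seq$fs_rf / 2),
                       type = "pass")
  out <- seq
  out$rf <- t(apply(seq$rf, 1, function(fr) signal::filtfilt(bf, fr)))
  out
}

#' Band-limited interpolation of RF frames
#'
#' Upsamples every frame by an integer factor using FFT zero-padding
#' (exact band-limited interpolation: the original samples are preserved).
#' The default factor 6 raises an 80 MHz sequence to 480 MHz, which sets
#' the displacement quantum of the tracker to about 1.6 um.
#'
#' @param seq an [echo_sequence()].
#' @param factor integer upsampling factor (>= 1).
#' @return An [echo_sequence()] with `factor` times the samples and
#'   sampling rate.
#' @export
interpolate_frames <- function(seq, factor = 6) {
  stopifnot(inherits(seq, "echo_sequence"))
  if (!is.numeric(factor) || factor < 1 || factor != round(factor))
    stop_arg("factor must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(seq)
  n <- ncol(seq$rf)
  K <- nrow(seq$rf)
  N <- n * factor
  half <- floor(n / 2)
  out <- matrix(0, K, N)
  chunk <- 256L
  for (i0 in seq(1L, K, by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, K)
    X <- stats::mvfft(t(seq$rf[idx, , drop = FALSE]))
    Y <- matrix(0 + 0i, N, length(idx))
    if (n %% 2 == 0) {
      Y[1:half, ] <- X[1:half, , drop = FALSE]
      Y[half + 1, ] <- X[half + 1, , drop = FALSE] / 2
      Y[N - half + 1, ] <- X[half + 1, , drop = FALSE] / 2
      if (half >= 2)
        Y[(N - half + 2):N, ] <- X[(half + 2):n, , drop = FALSE]
    } else {
      Y[1:(half + 1), ] <- X[1:(half + 1), , drop = FALSE]
      Y[(N - half + 1):N, ] <- X[(half + 2):n, , drop = FALSE]
    }
    out[idx, ] <- t(Re(stats::mvfft(Y, inverse = TRUE)) / n)
  }
  echo_sequence(out, fs_rf = seq$fs_rf * factor, prf = seq$prf,
                c = seq$c, z0_mm = seq$z0_mm)
}

#' Locate the two arterial wall echoes in a frame
#'
#' Computes the analytic-signal envelope of one frame, smooths it, and
#' returns the centres of the two largest envelope peaks separated by at
#' least `min_separation_mm`, ordered by depth (proximal first).
#'
#' @param seq an [echo_sequence()] (ideally bandpass-filtered).
#' @param frame frame index to analyse. Default 1.
#' @param min_separation_mm minimum wall separation, mm. Default 3.
#' @return List with `u_prox`, `u_dist` (sample indices, 1-based) and
#'   `depth_prox_mm`, `depth_dist_mm`.
#' @export
detect_walls <- function(seq, frame = 1, min_separation_mm = 3) {
  stopifnot(inherits(seq, "echo_sequence"))
  fr <- seq$rf[frame, ]
  env <- envelope(fr)
  w <- 9
  env_s <- as.numeric(stats::filter(env, rep(1 / w, w), sides = 2))
  env_s[is.na(env_s)] <- 0
  thr <- max(5 * stats::median(env), 0.2 * max(env_s))
  pk <- local_maxima(env_s)
  pk <- pk[env_s[pk] >= thr]
  if (length(pk) < 2)
    stop_arg("wall detection failed: fewer than two qualifying echo peaks")
  pk <- pk[order(env_s[pk], decreasing = TRUE)]
  sep <- min_separation_mm / sample_span_mm(seq)
  u1 <- pk[1]
  rest <- pk[abs(pk - u1) >= sep]
  if (length(rest) < 1)
    stop_arg("wall detection failed: echo peaks closer than %.1f mm",
             min_separation_mm)
  u2 <- rest[1]
  u <- sort(c(u1, u2))
  list(u_prox = u[1], u_dist = u[2],
       depth_prox_mm = seq$z0_mm + (u[1] - 1) * sample_span_mm(seq),
       depth_dist_mm = seq$z0_mm + (u[2] - 1) * sample_span_mm(seq))
}
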