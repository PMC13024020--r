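#' Region-of-interest specification for wall tracking
#'
#' @param center centre sample index of the wall echo window (1-based).
#' @param half_width half window length W in samples; the window spans
#'   `2W + 1` samples. Default 40 (80 samples at 80 MHz, about 0.77 mm).
#' @param delta integer shift search range `c(delta1, delta2)` in samples;
#'   must bracket zero.
#' @return A list of class `"roi_spec"`.
#' @export
roi_spec <- function(center, half_width = 40, delta = c(-40, 40)) {
  if (!(delta[1] <= 0 && delta[2] >= 0))
    stop_arg("delta range must bracket zero")
  if (half_width < 1) stop_arg("half_width must be >= 1")
  structure(list(center = as.integer(round(center)),
                 half_width = as.integer(half_width),
                 delta = as.integer(delta)),
            class = "roi_spec")
}

#' Cross-correlation curve between consecutive frames
#'
#' Computes the unnormalized cross-correlation
#' `C(delta) = sum_n G_k(n) G_{k+1}(n + delta)` over the ROI window for
#' every integer shift in the ROI's delta range.
#'
#' @param ref_frame,next_frame numeric vectors (same length).
#' @param roi an [roi_spec()].
#' @return List with `delta` (integer shifts) and `C` (correlation values).
#' @export
cross_correlation_curve <- function(ref_frame, next_frame, roi) {
  u <- roi$center; W <- roi$half_width
  d1 <- roi$delta[1]; d2 <- roi$delta[2]
  n <- length(ref_frame)
  if (u - W + d1 < 1 || u + W + d2 > n)
    stop_arg("ROI window exceeds frame bounds for some shift")
  seg <- ref_frame[(u - W):(u + W)]
  deltas <- d1:d2
  C <- vapply(deltas, function(d)
    sum(seg * next_frame[(u - W + d):(u + W + d)]), numeric(1))
  list(delta = deltas, C = C)
}

#' Estimate the frame-to-frame wall shift from a correlation curve
#'
#' The shift estimate is the negated argmax of the correlation curve.
#' Exact ties are broken toward the smallest absolute shift (then the
#' negative one), encoding a zero-motion prior. With `subsample = TRUE`
#' a parabolic vertex through the three points around the integer peak
#' refines the argmax before negation. A peak on the boundary of the
#' search range is flagged (possible probe motion beyond the range) and
#' not refined.
#'
#' @param curve output of [cross_correlation_curve()].
#' @param subsample logical; parabolic sub-sample refinement. Default TRUE.
#' @return The shift estimate in samples (positive = motion toward the
#'   transducer), with attribute `"boundary"` (logical).
#' @export
estimate_shift <- function(curve, subsample = TRUE) {
  C <- curve$C; d <- curve$delta
  if (!length(C)) stop_arg("empty correlation curve")
  cand <- which(C == max(C))
  i <- cand[order(abs(d[cand]), d[cand])][1]
  boundary <- (i == 1 || i == length(C))
  dstar <- as.numeric(d[i])
  if (subsample && !boundary) {
    cm <- C[i - 1]; c0 <- C[i]; cp <- C[i + 1]
    den <- cm - 2 * c0 + cp
    if (den < 0) dstar <- dstar + 0.5 * (cm - cp) / den
  }
  structure(-dstar, boundary = boundary)
}

#' Track one arterial wall across a frame sequence
#'
#' Runs consecutive-frame cross-correlation shift estimation with the ROI
#' centre advected by the running cumulative shift, so the window follows
#' the wall. Cumulative displacement is converted to micrometres via
#' `c / (2 * fs_rf)`; positive displacement is motion toward the
#' transducer.
#'
#' @param seq an [echo_sequence()], already filtered and interpolated as
#'   configured.
#' @param roi an [roi_spec()] in the sample units of `seq`.
#' @param wall_label `"proximal"` or `"distal"`.
#' @param subsample logical, sub-sample refinement (default TRUE).
#' @param max_boundary_frac error if more than this fraction of frames has
#'   a boundary-flagged shift. Default 0.1.
#' @return A list of class `"wall_track"`: `shifts` (samples, length
#'   frames - 1), `cumulative_um` (length frames, starts at 0),
#'   `wall_label`, `boundary` (logical vector).
#' @export
track_wall <- function(seq, roi, wall_label = c("proximal", "distal"),
                       subsample = TRUE, max_boundary_frac = 0.1) {
  stopifnot(inherits(seq, "echo_sequence"), inherits(roi, "roi_spec"))
  wall_label <- match.arg(wall_label)
  K <- nrow(seq$rf)
  shifts <- numeric(K - 1)
  boundary <- logical(K - 1)
  cum <- 0
  for (k in seq_len(K - 1)) {
    r <- roi
    r$center <- roi$center - as.integer(round(cum))
    cur <- cross_correlation_curve(seq$rf[k, ], seq$rf[k + 1, ], r)
    s <- estimate_shift(cur, subsample = subsample)
    shifts[k] <- as.numeric(s)
    boundary[k] <- attr(s, "boundary")
    cum <- cum + shifts[k]
  }
  if (mean(boundary) > max_boundary_frac)
    stop_arg("tracking quality: %.0f%% of shifts hit the search boundary",
             100 * mean(boundary))
  um_per_sample <- seq$c / (2 * seq$fs_rf) * 1e6
  structure(list(shifts = shifts,
                 cumulative_um = c(0, cumsum(shifts)) * um_per_sample,
                 wall_label = wall_label, boundary = boundary),
            class = "wall_track")
}

#' Distension waveform from two wall tracks
#'
#' `dd_k = dW_prox_k - dW_dist_k`: with positive displacement defined as
#' motion toward the transducer, dilation (proximal wall toward, distal
#' wall away) yields positive distension.
#'
#' @param prox,dist `"wall_track"` objects of equal length.
#' @param prf frame rate, Hz (sampling rate of the result).
#' @return A `"distension_waveform"` with `provenance = "tracked"`.
#' @export
compute_distension <- function(prox, dist, prf) {
  if (length(prox$cumulative_um) != length(dist$cumulative_um))
    stop_arg("wall tracks have different lengths")
  structure(list(dd = prox$cumulative_um - dist$cumulative_um,
                 fs = prf, provenance = "tracked", annotations = NULL),
            class = "distension_waveform")
}

#' Full echo-tracking pipeline: RF frames to distension waveform
#'
#' Bandpass-filters the frames, auto-detects the two wall echoes,
#' interpolates to the working rate (default 6x, 480 MHz from 80 MHz),
#' tracks both walls by cross-correlation and returns the distension
#' waveform.
#'
#' @param seq an [echo_sequence()] of raw frames.
#' @param band RF bandpass edges, Hz. Default `c(2e6, 8e6)`.
#' @param order bandpass order. Default 4.
#' @param interp_factor interpolation factor. Default 6.
#' @param half_width ROI half width at the original sampling rate.
#'   Default 40.
#' @param delta shift search range at the interpolated rate.
#'   Default `c(-40, 40)`.
#' @param subsample logical, sub-sample refinement. Default TRUE.
#' @return A `"distension_waveform"` (micrometres at the frame rate) with
#'   attribute `"walls"` giving the detected wall positions.
#' @export
track_distension <- function(seq, band = c(2e6, 8e6), order = 4,
                             interp_factor = 6, half_width = 40,
                             delta = c(-40, 40), subsample = TRUE) {
  stopifnot(inherits(seq, "echo_sequence"))
  filt <- bandpass_rf(seq, band[1], band[2], order)
  walls <- detect_walls(filt)
  up <- interpolate_frames(filt, interp_factor)
  hw <- as.integer(half_width * interp_factor)
  roi_p <- roi_spec((walls$u_prox - 1) * interp_factor + 1, hw, delta)
  roi_d <- roi_spec((walls$u_dist - 1) * interp_factor + 1, hw, delta)
  tp <- track_wall(up, roi_p, "proximal", subsample = subsample)
  td <- track_wall(up, roi_d, "distal", subsample = subsample)
  out <- compute_distension(tp, td, seq$prf)
  attr(out, "walls") <- walls
  out
}
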