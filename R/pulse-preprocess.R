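#' Bandpass-filter a distension waveform
#'
#' Zero-phase Butterworth bandpass (default 0.4-16 Hz, 4th order) removing
#' baseline drift and high-frequency noise while preserving pulse
#' morphology in the passband.
#'
#' @param dd a `"distension_waveform"` or numeric vector.
#' @param lo,hi band edges, Hz. Defaults 0.4 and 16.
#' @param order total filter order (even). Default 4.
#' @param fs sampling rate, Hz (taken from the waveform object when given).
#' @return Same type as the input, filtered.
#' @export
filter_distension <- function(dd, lo = 0.4, hi = 16, order = 4, fs = NULL) {
  obj <- NULL
  if (inherits(dd, "distension_waveform")) {
    obj <- dd; fs <- dd$fs; dd <- dd$dd
  }
  if (is.null(fs)) stop_arg("fs required for a bare numeric waveform")
  if (!(lo > 0 && lo < hi && hi < fs / 2))
    stop_arg("band must satisfy 0 < lo < hi < fs/2")
  if (order %% 2 != 0) stop_arg("order must be even")
  bf <- signal::butter(order / 2, c(lo, hi) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, dd)
  if (!is.null(obj)) { obj$dd <- y; obj } else y
}

#' Savitzky-Golay derivatives of a distension waveform
#'
#' First and second time derivatives via a 5-point quadratic
#' Savitzky-Golay differentiator; the second derivative is the
#' differentiator applied to the first derivative (cascade).
#'
#' @param dd_f filtered waveform (numeric vector or
#'   `"distension_waveform"`).
#' @param fs sampling rate, Hz (taken from the object when given).
#' @param window SG window length in samples (odd). Default 5.
#' @param polyorder SG polynomial order (< window). Default 2.
#' @return A list of class `"derivative_set"`: `dd_f` (um), `d1` (um/s),
#'   `d2` (um/s^2), `fs`.
#' @export
pulse_derivatives <- function(dd_f, fs = NULL, window = 5, polyorder = 2) {
  if (inherits(dd_f, "distension_waveform")) {
    fs <- dd_f$fs; dd_f <- dd_f$dd
  }
  if (is.null(fs)) stop_arg("fs required")
  if (window %% 2 == 0) stop_arg("window must be odd")
  if (polyorder >= window) stop_arg("polyorder must be < window")
  d1 <- signal::sgolayfilt(dd_f, p = polyorder, n = window, m = 1,
                           ts = 1 / fs)
  d2 <- signal::sgolayfilt(d1, p = polyorder, n = window, m = 1,
                           ts = 1 / fs)
  structure(list(dd_f = dd_f, d1 = d1, d2 = d2, fs = fs),
            class = "derivative_set")
}

#' Segment a distension waveform into cardiac cycles
#'
#' Detects maximum-slope (MS) events on the first derivative with an
#' adaptive threshold and a 0.3 s refractory period, then places each
#' cycle onset at the waveform minimum immediately preceding the MS event.
#' The end of beat i is the onset of beat i+1; only complete beats are
#' returned.
#'
#' @param der a `"derivative_set"` (from [pulse_derivatives()]).
#' @param refractory_s minimum spacing between MS events, s. Default 0.3.
#' @param threshold_frac adaptive threshold as a fraction of the upper
#'   d1 peak level. Default 0.5.
#' @return Data frame with columns `f1`, `f2` (1-based onset/end sample
#'   indices, `f2` exclusive end = next onset).
#' @export
segment_beats <- function(der, refractory_s = 0.3, threshold_frac = 0.5) {
  stopifnot(inherits(der, "derivative_set"))
  d1 <- der$d1; fs <- der$fs
  n <- length(d1)
  if (n < 2 * fs) stop_arg("segment must be at least 2 s long")
  pk <- local_maxima(d1)
  if (!length(pk)) stop_arg("no beats found: flat first derivative")
  thr <- threshold_frac * stats::quantile(d1[pk], 0.95, names = FALSE)
  if (thr <= 0) stop_arg("no beats found: no positive slope events")
  pk <- pk[d1[pk] >= thr]
  if (!length(pk)) stop_arg("no beats found above the slope threshold")
  # refractory: greedy keep of the largest peak within each 0.3 s cluster
  refr <- round(refractory_s * fs)
  keep <- integer(0)
  for (i in pk[order(d1[pk], decreasing = TRUE)]) {
    if (!length(keep) || all(abs(keep - i) >= refr)) keep <- c(keep, i)
  }
  ms <- sort(keep)
  # onset: foot of the upstroke = last non-positive-slope sample before
  # the MS event; falls back to the window minimum at segment edges
  onsets <- vapply(ms, function(i) {
    lo <- max(1, i - refr)
    nonpos <- which(d1[lo:(i - 1)] <= 0)
    o <- if (length(nonpos)) lo + nonpos[length(nonpos)] - 1
    else lo + which.min(der$dd_f[lo:i]) - 1
    # snap to the waveform foot minimum around the slope crossing
    a <- max(lo, o - 2); b <- min(i, o + 3)
    a + which.min(der$dd_f[a:b]) - 1
  }, numeric(1))
  onsets <- sort(unique(as.integer(onsets)))
  if (length(onsets) < 2) stop_arg("no complete beats found")
  data.frame(f1 = onsets[-length(onsets)], f2 = onsets[-1])
}

# next local extrema of x after index i (exclusive); returns index or NA
next_extremum <- function(idx_set, after) {
  idx_set <- idx_set[idx_set > after]
  if (length(idx_set)) idx_set[1] else NA_integer_
}

# keep dicrotic-notch candidates with a real rebound: the waveform must
# rise by >= 1% of the beat amplitude after the minimum
keep_prominent_minima <- function(w, cand, nb) {
  amp <- max(w) - min(w)
  cand[vapply(cand, function(i) {
    i < nb - 1 && max(w[i:nb]) - w[i] >= 0.01 * amp
  }, logical(1))]
}

#' Locate fiducial points within one beat
#'
#' Identifies the landmark points of pulse-wave analysis on one cardiac
#' cycle of the distension waveform and its derivatives: systolic peak
#' `s`, dicrotic notch `DN`, diastolic peak `DP`, early-systolic and
#' reflected-wave points `p1`/`p2` (with inflection / local-max variants
#' `p1in` / `p2pk`), first-derivative maxima `MS` / `MS2`, and the
#' `a`-`f` extrema of the second derivative. Points that cannot be
#' identified are set `NA` and recorded in `quality_flags`; only a
#' missing systolic peak is an error.
#'
#' @param der a `"derivative_set"` covering the whole record.
#' @param f1,f2 beat onset / end sample indices (from [segment_beats()]).
#' @return A list of class `"beat_annotation"` with 1-based absolute
#'   sample indices (`f1`, `f2`, `s`, `DN`, `DP`, `p1`, `p1in`, `p2`,
#'   `p2pk`, `MS`, `MS2`, `a`, `b`, `c`, `d`, `e`, `f`), plus `fs` and
#'   `quality_flags` (character vector naming absent optional points).
#' @export
locate_fiducials <- function(der, f1, f2) {
  stopifnot(inherits(der, "derivative_set"))
  fs <- der$fs
  if ((f2 - f1) / fs < 0.4) stop_arg("beat shorter than 0.4 s")
  idx <- f1:f2
  w <- der$dd_f[idx]; w1 <- der$d1[idx]; w2 <- der$d2[idx]
  nb <- length(idx)
  flags <- character(0)

  s_rel <- which.max(w)
  if (s_rel <= 1 || s_rel >= nb) stop_arg("no interior systolic peak")
  ms_rel <- which.max(w1[1:s_rel])

  max2 <- local_maxima(w2); min2 <- local_minima(w2)
  # a: largest d2 maximum on the upstroke; b: deepest d2 minimum between
  # a and just past the systolic peak
  a_cand <- max2[max2 <= s_rel]
  a_rel <- if (length(a_cand)) a_cand[which.max(w2[a_cand])] else NA
  b_rel <- NA
  if (!is.na(a_rel)) {
    b_cand <- min2[min2 > a_rel & min2 <= s_rel + 2]
    if (length(b_cand)) b_rel <- b_cand[which.min(w2[b_cand])]
  }
  # e: largest d2 maximum in mid-to-late systolic decline (the dicrotic
  # curvature); c/d: reflected-wave extrema between b and e; f: first
  # minimum after e
  n_beat <- nb
  e_lo <- s_rel + round(0.08 * n_beat); e_hi <- min(nb, s_rel + round(0.6 * n_beat))
  e_cand <- max2[max2 > e_lo & max2 <= e_hi]
  e_rel <- if (length(e_cand)) e_cand[which.max(w2[e_cand])] else NA
  c_rel <- d_rel <- f_rel <- NA
  if (!is.na(b_rel) && !is.na(e_rel)) {
    c_cand <- max2[max2 > b_rel & max2 < e_rel]
    if (length(c_cand)) c_rel <- c_cand[which.max(w2[c_cand])]
    if (!is.na(c_rel)) {
      d_cand <- min2[min2 > c_rel & min2 < e_rel]
      if (length(d_cand)) d_rel <- d_cand[which.min(w2[d_cand])]
    }
  }
  if (!is.na(e_rel)) f_rel <- next_extremum(min2, e_rel)

  # dicrotic notch: waveform minimum nearest the e-wave, falling back to
  # the first waveform minimum in [s, s + 0.4 T]
  T_b <- nb / fs
  dn_rel <- NA
  if (!is.na(e_rel)) {
    lo <- max(s_rel + 1, e_rel - round(0.1 * fs))
    hi <- min(nb, e_rel + round(0.1 * fs))
    mins_w <- local_minima(w[lo:hi])
    mins_w <- keep_prominent_minima(w, lo + mins_w - 1, nb)
    if (length(mins_w))
      dn_rel <- mins_w[which.min(abs(mins_w - e_rel))]
  } else {
    hi <- min(nb, s_rel + round(0.4 * T_b * fs))
    if (hi - s_rel > 2) {
      mins_w <- local_minima(w[s_rel:hi])
      mins_w <- keep_prominent_minima(w, s_rel + mins_w - 1, nb)
      if (length(mins_w)) dn_rel <- mins_w[1]
    }
  }
  if (is.na(dn_rel) || dn_rel <= s_rel || dn_rel >= nb) {
    dn_rel <- NA; flags <- c(flags, "DN")
  }

  # diastolic peak: first waveform maximum after DN
  dp_rel <- NA
  if (!is.na(dn_rel)) {
    maxw <- local_maxima(w)
    dp_rel <- next_extremum(maxw, dn_rel)
    if (is.na(dp_rel)) {
      tail_w <- (dn_rel + 1):nb
      if (length(tail_w) > 1) dp_rel <- tail_w[which.max(w[tail_w])]
    }
  }
  if (is.na(dp_rel)) flags <- c(flags, "DP")

  # MS2: largest d1 local maximum after DN
  ms2_rel <- NA
  if (!is.na(dn_rel)) {
    m1 <- local_maxima(w1)
    m1 <- m1[m1 > dn_rel]
    if (length(m1)) ms2_rel <- m1[which.max(w1[m1])]
  }
  if (is.na(ms2_rel)) flags <- c(flags, "MS2")

  # p1: early-systolic point at the b-wave time; p1in: first downward
  # d2 zero-crossing after a (upstroke inflection)
  p1_rel <- b_rel
  p1in_rel <- NA
  if (!is.na(a_rel)) {
    zc <- which(w2[-nb] > 0 & w2[-1] <= 0)
    zc <- zc[zc >= a_rel & zc <= s_rel + 2]
    if (length(zc)) p1in_rel <- zc[1]
  }
  if (is.na(p1in_rel)) p1in_rel <- p1_rel
  if (is.na(p1_rel)) flags <- c(flags, "p1")

  # p2: reflected-wave point at the d-wave time; p2pk: nearest waveform
  # local maximum (systolic shoulder), falling back to the d-wave time
  p2_rel <- d_rel
  p2pk_rel <- NA
  if (!is.na(d_rel)) {
    maxw <- local_maxima(w)
    near <- maxw[maxw > s_rel & (is.na(dn_rel) | maxw < dn_rel)]
    if (length(near)) p2pk_rel <- near[which.min(abs(near - d_rel))]
    if (is.na(p2pk_rel) || abs(p2pk_rel - d_rel) > 0.1 * fs)
      p2pk_rel <- d_rel
  }
  if (is.na(p2_rel)) flags <- c(flags, "p2")
  if (!length(flags)) flags <- character(0)

  abs_or_na <- function(r)
    if (is.na(r)) NA_integer_ else as.integer(f1) + as.integer(r) - 1L
  structure(list(
    f1 = as.integer(f1), f2 = as.integer(f2), s = abs_or_na(s_rel),
    DN = abs_or_na(dn_rel), DP = abs_or_na(dp_rel),
    p1 = abs_or_na(p1_rel), p1in = abs_or_na(p1in_rel),
    p2 = abs_or_na(p2_rel), p2pk = abs_or_na(p2pk_rel),
    MS = abs_or_na(ms_rel), MS2 = abs_or_na(ms2_rel),
    a = abs_or_na(a_rel), b = abs_or_na(b_rel), c = abs_or_na(c_rel),
    d = abs_or_na(d_rel), e = abs_or_na(e_rel), f = abs_or_na(f_rel),
    fs = fs, quality_flags = flags),
    class = "beat_annotation")
}
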