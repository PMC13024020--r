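#' Canonical registry of the 52 morphological features
#'
#' One row per feature: id (`F1`..`F52`), canonical name, and category
#' (`time` - time intervals and ratios; `amplitude` - relative
#' amplitudes; `slope`; `area`). The partition is 25 / 21 / 2 / 4.
#'
#' @return Data frame with columns `id`, `name`, `category`.
#' @export
feature_registry <- function() {
  reg <- rbind(
    data.frame(id = paste0("F", 1:6),
               name = c("t_a", "t_b", "t_c", "t_d", "t_e", "t_f"),
               category = "time"),
    data.frame(id = paste0("F", 7:13),
               name = c("tsys", "tDN", "tDP", "tp1", "tp2pk", "tMS", "tMS2"),
               category = "time"),
    data.frame(id = "F14", name = "STT", category = "amplitude"),
    data.frame(id = paste0("F", 15:26),
               name = c("T", "IHR", "dT", "SI", "prop_s", "Tdia", "Tratio",
                        "prop_dT", "Tp1_dia", "Tp2pk_dia", "Tb_c", "Tb_d"),
               category = "time"),
    data.frame(id = paste0("F", 27:33),
               name = c("amp_p1", "amp_p2", "AIx", "RI_p1", "RI_p2",
                        "ratio_p2_p1", "RI"),
               category = "amplitude"),
    data.frame(id = paste0("F", 34:36), name = c("A1", "A2", "IPA"),
               category = "area"),
    data.frame(id = "F37", name = "ms_div_am", category = "amplitude"),
    data.frame(id = paste0("F", 38:41),
               name = c("b_div_a", "c_div_a", "d_div_a", "e_div_a"),
               category = "amplitude"),
    data.frame(id = paste0("F", 42:46),
               name = c("a_div_amp", "b_div_amp", "c_div_amp", "d_div_amp",
                        "e_div_amp"),
               category = "amplitude"),
    data.frame(id = paste0("F", 47:49),
               name = c("AGI", "AGI_inf", "AGI_mod"),
               category = "amplitude"),
    data.frame(id = paste0("F", 50:51),
               name = c("slope_b_c", "slope_b_d"), category = "slope"),
    data.frame(id = "F52", name = "IPAD", category = "area"))
  rownames(reg) <- NULL
  reg
}

#' Verify the feature-registry category tally
#'
#' @param registry a feature registry (default the canonical one).
#' @return Named integer vector `c(time, amplitude, slope, area)`; errors
#'   if the tally is not 25/21/2/4 summing to 52.
#' @export
feature_count_check <- function(registry = feature_registry()) {
  tally <- c(time = sum(registry$category == "time"),
             amplitude = sum(registry$category == "amplitude"),
             slope = sum(registry$category == "slope"),
             area = sum(registry$category == "area"))
  if (!identical(unname(tally), c(25L, 21L, 2L, 4L)) ||
      nrow(registry) != 52)
    stop("feature registry integrity error: expected 25/21/2/4 = 52 features",
         call. = FALSE)
  tally
}

#' Extract the 52 morphological features from one beat
#'
#' Computes every registry feature from a beat's fiducial annotation and
#' signal windows. Times are in seconds relative to the cycle onset `f1`;
#' `amp` is the peak-minus-trough amplitude of the beat on the filtered
#' waveform; point amplitudes are read on the waveform (baseline =
#' beat trough) for waveform points and on the first / second derivative
#' for `MS` and the `a`-`f` waves; areas are trapezoidal integrals of the
#' baseline-corrected beat (um*s). A feature whose fiducial dependencies
#' are absent is `NA`, never silently zero.
#'
#' @param ann a `"beat_annotation"`.
#' @param der the `"derivative_set"` the annotation indexes into.
#' @param height subject height in metres (for the systolic index).
#' @return Named numeric vector of length 52 (names = registry names).
#' @export
extract_beat_features <- function(ann, der, height = NA_real_) {
  stopifnot(inherits(ann, "beat_annotation"),
            inherits(der, "derivative_set"))
  fs <- der$fs
  idx <- ann$f1:ann$f2
  w <- der$dd_f[idx]
  base <- min(w)
  amp <- max(w) - base
  if (!(amp > 0)) stop_arg("non-positive beat amplitude")

  tm <- function(i) if (is.na(i)) NA_real_ else (i - ann$f1) / fs
  aw <- function(i) if (is.na(i)) NA_real_ else der$dd_f[i] - base  # waveform amp
  a1 <- function(i) if (is.na(i)) NA_real_ else der$d1[i]           # d1 value
  a2 <- function(i) if (is.na(i)) NA_real_ else der$d2[i]           # d2 value

  t_a <- tm(ann$a); t_b <- tm(ann$b); t_c <- tm(ann$c)
  t_d <- tm(ann$d); t_e <- tm(ann$e); t_f <- tm(ann$f)
  tsys <- tm(ann$s); tDN <- tm(ann$DN); tDP <- tm(ann$DP)
  tp1 <- tm(ann$p1); tp2pk <- tm(ann$p2pk)
  tMS <- tm(ann$MS); tMS2 <- tm(ann$MS2)
  T <- (ann$f2 - ann$f1) / fs

  amp_a <- a2(ann$a); amp_b <- a2(ann$b); amp_c <- a2(ann$c)
  amp_d <- a2(ann$d); amp_e <- a2(ann$e)
  ms <- a1(ann$MS)
  amp_p1 <- aw(ann$p1); amp_p2 <- aw(ann$p2)
  amp_p1in <- aw(ann$p1in); amp_p2pk <- aw(ann$p2pk)
  amp_DP <- aw(ann$DP); amp_dia <- amp_DP

  dt <- 1 / fs
  A1 <- A2 <- NA_real_
  if (!is.na(ann$DN)) {
    A1 <- trapz_int(der$dd_f[ann$f1:ann$DN] - base, dt)
    A2 <- trapz_int(der$dd_f[ann$DN:ann$f2] - base, dt)
  }
  IPA <- A2 / A1

  Tdia <- if (is.na(tDN)) NA_real_ else T - tDN
  out <- c(
    t_a = t_a, t_b = t_b, t_c = t_c, t_d = t_d, t_e = t_e, t_f = t_f,
    tsys = tsys, tDN = tDN, tDP = tDP, tp1 = tp1, tp2pk = tp2pk,
    tMS = tMS, tMS2 = tMS2,
    STT = amp / tsys,
    T = T, IHR = 60 / T, dT = tDN - tsys, SI = tsys / height,
    prop_s = tsys / T, Tdia = Tdia, Tratio = tDN / Tdia,
    prop_dT = (tDN - tsys) / T,
    Tp1_dia = tDP - tp1, Tp2pk_dia = tDP - tp2pk,
    Tb_c = t_c - t_b, Tb_d = t_d - t_b,
    amp_p1 = amp_p1 / amp, amp_p2 = amp_p2 / amp,
    AIx = 100 * (amp_p2pk - amp_p1in) / amp,
    RI_p1 = amp_dia / amp_p1, RI_p2 = amp_dia / amp_p2,
    ratio_p2_p1 = amp_p2 / amp_p1, RI = amp_DP / amp,
    A1 = A1, A2 = A2, IPA = IPA,
    ms_div_am = ms / amp,
    b_div_a = amp_b / amp_a, c_div_a = amp_c / amp_a,
    d_div_a = amp_d / amp_a, e_div_a = amp_e / amp_a,
    a_div_amp = amp_a / amp, b_div_amp = amp_b / amp,
    c_div_amp = amp_c / amp, d_div_amp = amp_d / amp,
    e_div_amp = amp_e / amp,
    AGI = (amp_b - amp_c - amp_d - amp_e) / amp_a,
    AGI_inf = (amp_b - amp_e) / amp_a,
    AGI_mod = (amp_b - amp_c - amp_d) / amp_a,
    # slope_b_c printed with the same formula as slope_b_d in the source
    # table (apparent typo); kept as printed, while slope_b_d honours its
    # name
    slope_b_c = (amp_d - amp_b) / (t_c - t_d),
    slope_b_d = (amp_d - amp_b) / (t_d - t_b),
    IPAD = IPA + amp_d / amp_a)
  stopifnot(identical(names(out), feature_registry()$name))
  out
}

#' Aggregate per-beat features into one record-level vector
#'
#' Per-feature median across the beats of a record, ignoring absent
#' values; a feature present in fewer than half the beats is absent in
#' the aggregate. Records with fewer than three valid beats are rejected.
#'
#' @param beat_matrix numeric matrix, beats x 52 features (rows from
#'   [extract_beat_features()]).
#' @return Named numeric vector of length 52.
#' @export
aggregate_record <- function(beat_matrix) {
  if (is.null(dim(beat_matrix))) beat_matrix <- rbind(beat_matrix)
  if (nrow(beat_matrix) < 3)
    stop_arg("record rejected: fewer than 3 valid beats")
  apply(beat_matrix, 2, function(v) {
    ok <- is.finite(v)
    if (mean(ok) < 0.5) NA_real_ else stats::median(v[ok])
  })
}

#' Features of one distension record
#'
#' Full per-record feature pipeline: optional 0.4-16 Hz bandpass,
#' Savitzky-Golay derivatives, beat segmentation, fiducial detection per
#' beat, 52 features per beat, median aggregation across beats.
#'
#' @param dd a `"distension_waveform"` or numeric vector.
#' @param fs sampling rate (when `dd` is a bare vector).
#' @param height subject height, m.
#' @param bandpass logical, apply the 0.4-16 Hz filter first (default
#'   TRUE; disable for drift-free synthetic segments).
#' @return Named numeric vector of 52 features with attribute `n_beats`.
#' @export
extract_record_features <- function(dd, fs = NULL, height = NA_real_,
                                    bandpass = TRUE) {
  if (inherits(dd, "distension_waveform")) { fs <- dd$fs; dd <- dd$dd }
  if (is.null(fs)) stop_arg("fs required")
  x <- if (bandpass) filter_distension(dd, fs = fs) else dd
  der <- pulse_derivatives(x, fs)
  beats <- segment_beats(der)
  rows <- list()
  for (k in seq_len(nrow(beats))) {
    ann <- try(locate_fiducials(der, beats$f1[k], beats$f2[k]),
               silent = TRUE)
    if (inherits(ann, "try-error")) next
    fv <- try(extract_beat_features(ann, der, height), silent = TRUE)
    if (!inherits(fv, "try-error")) rows[[length(rows) + 1]] <- fv
  }
  if (length(rows) < 3)
    stop_arg("record rejected: fewer than 3 valid beats")
  out <- aggregate_record(do.call(rbind, rows))
  attr(out, "n_beats") <- length(rows)
  out
}
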