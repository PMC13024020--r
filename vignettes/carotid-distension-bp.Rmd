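---
title: "Methods: carotid distension pulse wave analysis for SBP estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: carotid distension pulse wave analysis for SBP estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Arterial blood pressure shapes the pulse waveform: changes in cardiac
output shorten the systolic upstroke, and changes in peripheral
resistance alter the timing and size of the reflected wave. Pulse wave
analysis (PWA) exploits this by mapping waveform morphology to blood
pressure with a learned model. Most PWA work uses photoplethysmography,
whose volume signal is distorted by smooth-muscle tone and skin optics.
The carotid artery diameter **distension waveform** ΔD(t) — the
time-varying change of lumen diameter measured by ultrasound — is a more
direct mechanical correlate of central pressure: in large elastic
arteries the diameter–pressure relation is close to linear over a
cardiac cycle.

`carotidpwa` implements the full chain from raw A-mode radio-frequency
(RF) echoes to per-subject systolic blood pressure (SBP) estimates, plus
a synthetic data generator that stands in for the (non-public) human
dataset with a known ground truth.

## Echo tracking

Each emission yields one RF frame (80 MHz sampling; 200 Hz frame rate,
which becomes the sampling rate of ΔD(t)). Processing per the classic
cross-correlation approach:

* 2–8 MHz 4th-order Butterworth bandpass per frame, applied
  forward–backward. Zero-phase filtering is a deliberate choice: causal
  filtering would bias echo positions and therefore absolute wall
  delays.
* Band-limited interpolation ×6 (FFT zero padding, exact on the original
  grid) to 480 MHz. One interpolated sample corresponds to
  c/(2·f_s) ≈ 1.6 µm of two-way displacement — the tracker's quantum.
* Wall auto-identification: the two largest analytic-envelope peaks
  separated by ≥3 mm, ordered by depth.
* For each wall, an ROI of 80 raw samples (0.77 mm) centred on the echo.
  The unnormalized cross-correlation between consecutive frames is
  maximized over integer shifts δ ∈ [−40, 40] (interpolated samples,
  ≈ ±64 µm/frame — ample for physiological wall velocity plus probe
  drift); the shift estimate is the negated argmax. The printed equation
  is an integer argmax; sub-sample parabolic refinement is ON by default
  and an integer mode reproduces the literal rule. Ties break toward the
  smallest |δ| (zero-motion prior). A peak on the range boundary is
  flagged; more than 10% flagged frames aborts the track.
* The ROI centre is advected by the running cumulative shift so the
  window follows the wall — without this, drifts larger than the window
  would break the track. Consecutive-frame referencing (k vs k+1) is
  used throughout; no fixed-reference mode.
* Distension is the difference of the cumulative wall displacements,
  ΔD = ΔW_prox − ΔW_dist, positive on dilation.

Numerical properties checked by the tests: exact recovery of all integer
translations in the search range; per-frame quantization error ≤ half a
sample in integer mode; end-to-end RMSE against generated ground truth
< 5 µm noiseless (measured ≈ 0.06 µm) and < 15 µm at 20 dB RF SNR
(measured 3–9 µm across seeds).

## Pulse preprocessing and fiducials

ΔD(t) is bandpass-filtered 0.4–16 Hz (4th order, zero phase) to remove
baseline drift while keeping pulse morphology; derivatives use a 5-point
quadratic Savitzky–Golay differentiator, cascaded for the second
derivative. The derivative ambiguity (filtered vs raw input) is resolved
in favour of the filtered waveform, since fiducial detection runs on it.

Cycle onsets are placed at the upstroke foot: maximum-slope (MS) events
are detected on the first derivative with an adaptive threshold (half the
95th percentile of slope peaks) and a 0.3 s refractory period; the onset
is the last non-positive-slope sample before MS, snapped to the local
waveform minimum. An earlier "deepest minimum before MS" rule proved
fragile — the decaying dicrotic oscillation's second dip can be deeper
than the onset foot — whereas the upstroke-foot rule is the standard
convention and recovers generated onsets exactly.

Within each beat: `s` is the waveform maximum; `a`/`b` are the largest
second-derivative maximum on the upstroke and the deepest following
minimum; `e` is the largest d2 maximum in mid-to-late systolic decline
(the dicrotic curvature), with `c`/`d` the reflected-wave extrema between
`b` and `e` and `f` the first minimum after `e`. The dicrotic notch is
the waveform minimum nearest `e` (fallback: first prominent minimum in
[s, s + 0.4 T]); a candidate must rebound by ≥1% of the beat amplitude,
so symmetric beats without a dicrotic component yield an absent, flagged
DN rather than a numerically spurious one. `p1`/`p2` follow the b-wave /
d-wave timing convention with an inflection variant (`p1in`, from the d2
zero-crossing) and a local-maximum variant (`p2pk`). Mandatory points
(f1, s, f2) missing ⇒ the beat is dropped; optional points missing ⇒
flagged and propagated as absent features, never silently zero.

## The 52-feature registry

Features are computed exactly per their defining formulas: 25 time
intervals and ratios (fiducial times relative to f1, cycle duration T,
instantaneous heart rate 60/T, systolic proportion, systolic index
tsys/height with height in metres, …), 21 relative amplitudes (waveform
amplitudes relative to the beat's peak-to-trough amplitude; d1/d2 values
at MS and the a–f waves; augmentation index
100·(amp_p2pk − amp_p1in)/amp; aging indices), 2 slopes and 4 area
features (trapezoidal integrals of the baseline-corrected beat on both
sides of the notch, their ratio IPA, and IPAD = IPA + d/a). Two printed
slope rows share one formula in the source table — an apparent typo; the
first is implemented as printed, the second per its name
(amp_d − amp_b)/(t_d − t_b), and both are noted here. Per-record
aggregation is the median across beats, requiring ≥3 valid beats and
≥50% presence per feature.

## Personalized calibration

One model per subject, following the classic R modelling idiom:
`bp_model(sbp_mmhg ~ ., data, method =)` returns a classed object with
`predict`/`coef`/`residuals`/`summary` methods. Methods: random forest
(500 trees), gradient boosting (300 rounds, learning rate 0.05, depth 3),
ordinary least squares, and the mean-value model (MVM) baseline that
predicts the training mean. Hyperparameters are fixed config — the study
this replicates states none — and every stochastic component is
explicitly seeded.

Feature ranking uses each model family's internal importance (node-purity
gain for the trees, absolute standardized coefficients for MLR), is
computed per subject on the training split only, and feeds (a) the
composite cross-subject score (rank r ≤ 20 contributes 21 − r points,
summed over subjects) and (b) the candidate grid for selection. The
per-subject "best" configuration is chosen by 5-fold cross-validated MAE
on the training split over {MLR, RF, XGB} × top-n features, n ≤ 20; the
selection criterion is unstated in the source study, and selecting on the
test split would leak, so CV is the defensible choice. Ties prefer fewer
features, then the simpler model. Missing feature values are imputed by
training-split medians. Pooled metrics are record-weighted across
subjects (per-subject metrics are also retained); MAE ± SD means the mean
and standard deviation of absolute errors.

## The synthetic generator

The generator defines the study conditions; its defaults are fixed once:

* Cohort of 14 subjects; baseline SBP ~ N(125, 10²) mmHg truncated to
  [90, 160]; heights U(1.55, 1.95) m; carotid walls near 15/22 mm depth.
* Four session groups: two training (≈39 records together), a same-day
  test session (≈19), and a follow-up (≈24), each with rest,
  cold-pressor (peak rise drawn U(17, 23) mmHg — the protocol extends
  immersion until the rise exceeds 15 mmHg), recovery, and post-exercise
  phases (peak U(26, 32) mmHg decaying monotonically to baseline; heart
  rate elevated ~28 bpm and decaying). Within-session SBP range thus
  exceeds 25 mmHg and the mean stressed-record rise is ~13–15 mmHg.
  Record labels add N(0, 2²) mmHg of reference-device noise.
* Each 12 s record is a concatenation of analytic beats: a systolic
  Gaussian lobe (σ = rise time / 3.5), a reflected Gaussian at
  delay ~0.12 s with twice the width (reflected waves arrive dispersed —
  a narrow reflected lobe would form a spurious second upstroke), an
  exponentially decaying dicrotic oscillation, and a small (0.8% of
  amplitude) pre-systolic foot dip that makes the onset a strict
  waveform minimum, as in measured distension pulses. Every fiducial of
  the continuous model is located on a dense auxiliary grid and stored
  as ground truth. SBP deviation from baseline maps linearly to rise
  time (−0.4%/mmHg), reflection delay (−0.5%/mmHg), reflection amplitude
  (+0.6%/mmHg) and pulse amplitude (+0.4%/mmHg); these magnitudes are
  config inventions (the directions follow pressure physiology; no
  published per-mmHg values exist for distension morphology), with ±15%
  inter-subject variation and 2% beat-to-beat jitter.
* RF frames carry two Gaussian-enveloped 5 MHz tone-burst wall echoes
  with the distension split symmetrically across the walls, static
  tissue speckle (seeded scatterers convolved with the pulse, amplitude
  ≤ 1/5 of the wall echo, placed only outside the lumen/pulsation zone —
  blood speckle decorrelates and periarterial tissue moves with the
  wall, and static in-lumen clutter would exert an unphysical persistent
  pull on the tracker), and white noise set by an SNR knob.
* Long-term (group 4) records perturb the subject's morphology baselines
  by a seeded 2% relative drift, emulating the physiological changes
  that degrade calibration after days.

What passing tests show — and do not show. The generator's morphology-SBP
coupling is noiseless and low-dimensional, so model-layer results on
synthetic data (e.g. best-model MAE ≈ 0.3–0.4 × MVM MAE) demonstrate that
the pipeline recovers a recoverable signal, not that the accuracy figures
transfer to humans; real waveforms add probe-angle variation, motion
artifacts, arrhythmia and morphology components the template lacks.

## Numerical choices and degenerate inputs

0-based sample arithmetic is avoided: all indices are 1-based R
convention, times in seconds from segment start. Constant or flat inputs
raise descriptive errors (segmentation, ranking on a constant target,
empty test sets). Correlation ties break deterministically; the
boundary-flag rate guards runaway tracks; records with fewer than three
valid beats are rejected with a reason. Problem sizes used in the tests
and acceptance script — 12 s records, 1,000-beat fiducial sweeps, a
14-subject study — match the emulated protocol.

## Known limitations

* Absolute arterial diameter is out of scope (single-element A-mode
  cannot measure it reliably); all amplitude features are relative.
* Consecutive-frame tracking accumulates error as a random walk; a
  fixed-reference or hybrid mode is not provided.
* The beat template cannot represent arrhythmic or biphasic-systole
  morphologies; fiducial fallbacks are tuned to single-notch pulses.
* DBP is not modelled; the fitting objective is SBP only.
* HDF5 echo containers are not supported; the binary int16 + JSON
  sidecar container carries the same metadata keys.
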