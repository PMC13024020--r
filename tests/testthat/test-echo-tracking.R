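make_seq <- function(frames, fs_rf = 80e6, z0_mm = 10) {
  echo_sequence(do.call(rbind, frames), fs_rf = fs_rf, prf = 200,
                z0_mm = z0_mm)
}

test_that("RF bandpass preserves the carrier and rejects out-of-band", {
  z <- make_seq(list(numeric(1870), numeric(1870)))
  expect_equal(bandpass_rf(z)$rf, z$rf)

  t <- (0:1869) / 80e6
  tone <- function(f) sin(2 * pi * f * t)
  s5 <- make_seq(list(tone(5e6), tone(5e6)))
  out5 <- bandpass_rf(s5)$rf[1, 200:1600]
  expect_gte(mean(out5^2), 0.9 * mean(tone(5e6)[200:1600]^2))
  s02 <- make_seq(list(tone(0.2e6), tone(0.2e6)))
  out02 <- bandpass_rf(s02)$rf[1, 200:1600]
  expect_lt(10 * log10(mean(out02^2) / mean(tone(0.2e6)[200:1600]^2)),
            -20)
  expect_error(bandpass_rf(s5, lo = 8e6, hi = 2e6), "band")
})

test_that("FFT interpolation is exact on the original grid", {
  fp <- synth_frame_pair()
  s <- make_seq(list(fp$ref, fp$ref))
  expect_identical(interpolate_frames(s, 1), s)
  up <- interpolate_frames(s, 6)
  expect_equal(up$fs_rf, 480e6)
  expect_equal(ncol(up$rf), 6 * ncol(s$rf))
  orig_idx <- seq(1, ncol(up$rf), by = 6)
  expect_lt(max(abs(up$rf[1, orig_idx] - s$rf[1, ])) /
              max(abs(s$rf[1, ])), 1e-6)
  expect_error(interpolate_frames(s, 0), "factor")
})

test_that("interpolated tone matches the analytic sinusoid", {
  n <- 1024
  t <- (0:(n - 1)) / 80e6
  tone <- sin(2 * pi * 5e6 * t)
  s <- make_seq(list(tone, tone))
  up <- interpolate_frames(s, 6)
  t_up <- (0:(6 * n - 1)) / 480e6
  ref <- sin(2 * pi * 5e6 * t_up)
  core <- 100:(6 * n - 100)  # away from the circular boundary
  expect_lt(max(abs(up$rf[1, core] - ref[core])), 0.01)
})

test_that("wall detection finds the injected echo depths", {
  fp <- synth_frame_pair(depth1 = 15, depth2 = 23)
  s <- make_seq(list(fp$ref, fp$ref))
  w <- detect_walls(s)
  expect_lt(abs(w$depth_prox_mm - 15), 0.2)
  expect_lt(abs(w$depth_dist_mm - 23), 0.2)

  set.seed(4)
  noise <- matrix(rnorm(2 * 1870, 0, 1), 2)
  expect_error(detect_walls(echo_sequence(noise, z0_mm = 10)),
               "fewer than two")
  close_fp <- synth_frame_pair(depth1 = 15, depth2 = 16.5)
  expect_error(detect_walls(make_seq(list(close_fp$ref, close_fp$ref)),
                            min_separation_mm = 3),
               "closer than")
})

test_that("cross-correlation curve matches its definition", {
  fp <- synth_frame_pair(shift_samples = 0)
  roi <- roi_spec(detect_walls(make_seq(list(fp$ref, fp$ref)))$u_prox,
                  40, c(-10, 10))
  cur <- cross_correlation_curve(fp$ref, fp$ref, roi)
  expect_equal(cur$delta[which.max(cur$C)], 0)

  # next frame advanced by 3 samples: argmax at -3, checked brute force
  nxt <- c(fp$ref[-(1:3)], numeric(3))
  cur3 <- cross_correlation_curve(fp$ref, nxt, roi)
  brute <- vapply(-10:10, function(d) {
    u <- roi$center; W <- roi$half_width
    sum(fp$ref[(u - W):(u + W)] * nxt[(u - W + d):(u + W + d)])
  }, numeric(1))
  expect_equal(cur3$C, brute)
  expect_equal(cur3$delta[which.max(cur3$C)], -3)

  # disjoint supports: identically zero
  a <- c(rep(0, 50), 1, 1, rep(0, 148))
  b <- c(rep(0, 150), 1, 1, rep(0, 48))
  curz <- cross_correlation_curve(a, b, roi_spec(51, 5, c(-5, 5)))
  expect_true(all(curz$C == 0))
  expect_error(cross_correlation_curve(a, b, roi_spec(3, 5, c(-5, 5))),
               "bounds")
})

test_that("shift estimation negates the argmax with tie and boundary rules", {
  expect_equal(as.numeric(estimate_shift(
    list(delta = -5:5, C = c(0:5, 4:0)), subsample = FALSE)), 0)
  C3 <- c(0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0)
  expect_equal(as.numeric(estimate_shift(
    list(delta = -5:5, C = C3), subsample = FALSE)), 3)
  # tie at equal C: smallest |delta|, then negative, wins
  expect_equal(as.numeric(estimate_shift(
    list(delta = -2:2, C = c(1, 1, 0, 1, 0)), subsample = FALSE)), 1)
  s <- estimate_shift(list(delta = -2:2, C = c(5, 1, 0, 1, 0)))
  expect_true(attr(s, "boundary"))
})

test_that("sub-sample refinement resolves a half-sample shift", {
  g <- function(x) cos(2 * pi * 0.0625 * x) * exp(-x^2 / (2 * 6.4^2))
  x <- 1:600
  ref <- g(x - 300)
  nxt <- g(x - 300.5)
  roi <- roi_spec(300, 40, c(-6, 6))
  cur <- cross_correlation_curve(ref, nxt, roi)
  est <- as.numeric(estimate_shift(cur, subsample = TRUE))
  # dense-grid oracle over continuous shifts of the analytic echo
  dense <- seq(-2, 2, by = 0.01)
  Cd <- vapply(dense, function(d)
    sum(ref[260:340] * g(x[260:340] + d - 300.5)), numeric(1))
  oracle <- -dense[which.max(Cd)]  # negated argmax of the dense curve
  expect_lt(abs(est - oracle), 0.25)
  expect_lt(abs(est + 0.5), 0.25)
})

test_that("exhaustive integer translations are recovered exactly", {
  fp <- synth_frame_pair()
  n <- length(fp$ref)
  roi <- roi_spec(round((15 - 10) / (1540 / (2 * 80e6) * 1e3)) + 1,
                  40, c(-40, 40))
  for (tr in seq(-40, 40, by = 5)) {
    nxt <- if (tr > 0) c(fp$ref[-seq_len(tr)], numeric(tr))
    else if (tr == 0) fp$ref
    else c(numeric(-tr), fp$ref[1:(n + tr)])
    # content of nxt at sample m equals ref at m + tr
    cur <- cross_correlation_curve(fp$ref, nxt, roi)
    expect_equal(as.numeric(estimate_shift(cur, subsample = FALSE)), tr)
  }
})

test_that("wall tracking integrates shifts into micrometres", {
  # static frames: exactly zero in integer mode, < 0.01 um refined
  fp <- synth_frame_pair()
  s <- make_seq(rep(list(fp$ref), 12))
  roi <- roi_spec(detect_walls(s)$u_prox, 40, c(-10, 10))
  tr <- track_wall(s, roi, "proximal", subsample = FALSE)
  expect_true(all(tr$cumulative_um == 0))
  expect_identical(tr$cumulative_um[1], 0)
  tr_ref <- track_wall(s, roi_spec(500, 40, c(-10, 10)), "proximal")
  expect_lt(max(abs(tr_ref$cumulative_um)), 0.01)

  # 1 sample/frame advance at 480 MHz: 10 frames -> ~16.0 um
  g <- function(x) cos(2 * pi * 0.0625 * x) * exp(-x^2 / (2 * 40^2))
  frames <- lapply(0:10, function(k) g((1:4000) - 2000 + k))
  s480 <- echo_sequence(do.call(rbind, frames), fs_rf = 480e6, prf = 200)
  tr2 <- track_wall(s480, roi_spec(2000, 240, c(-40, 40)), "proximal",
                    subsample = FALSE)
  expect_equal(tr2$cumulative_um[11], 10 * 1540 / (2 * 480e6) * 1e6,
               tolerance = 1e-6)
  expect_equal(tr2$cumulative_um[11], 16.04, tolerance = 1e-3)
})

test_that("distension is the proximal minus distal displacement", {
  z <- structure(list(cumulative_um = rep(0, 5)), class = "wall_track")
  d0 <- compute_distension(z, z, 200)
  expect_true(all(d0$dd == 0))
  p <- structure(list(cumulative_um = c(0, 10)), class = "wall_track")
  d <- structure(list(cumulative_um = c(0, -15)), class = "wall_track")
  expect_equal(compute_distension(p, d, 200)$dd[2], 25)
  expect_error(compute_distension(p, z, 200), "length")
})

test_that("noise-free echo round trip recovers the distension waveform", {
  prof <- test_profile()
  prof$noise_level <- 0
  dw <- synthesize_distension_segment(prof, prof$baseline_sbp + 10, 72,
                                      3, 200, seed = 2)
  es <- synthesize_echo_frames(dw, prof, rf_config = list(noise_level = 0),
                               seed = 1)
  expect_identical(nrow(es$rf), length(dw$dd))
  tr <- track_distension(es)
  err <- (tr$dd - tr$dd[1]) - (dw$dd - dw$dd[1])
  expect_lt(sqrt(mean(err^2)), 5)

  # single-wall track against the known sinusoidal wall motion
  prox_truth <- (dw$dd - dw$dd[1]) / 2
  filt <- bandpass_rf(es)
  up <- interpolate_frames(filt, 6)
  w <- detect_walls(filt)
  tw <- track_wall(up, roi_spec((w$u_prox - 1) * 6 + 1, 240, c(-40, 40)),
                   "proximal")
  expect_lt(sqrt(mean((tw$cumulative_um - prox_truth)^2)), 2)
})

test_that("zero distension gives bit-identical noiseless frames", {
  prof <- test_profile()
  dd0 <- structure(list(dd = rep(0, 24), fs = 200,
                        provenance = "synthetic", annotations = NULL),
                   class = "distension_waveform")
  es <- synthesize_echo_frames(dd0, prof, rf_config = list(noise_level = 0))
  expect_true(all(es$rf == rep(es$rf[1, ], each = nrow(es$rf))))
})

test_that("a 77 um distension step moves the distal echo by 4 samples", {
  prof <- test_profile()
  dd <- structure(list(dd = c(0, 77), fs = 200, provenance = "synthetic",
                       annotations = NULL), class = "distension_waveform")
  es <- synthesize_echo_frames(dd, prof, rf_config = list(noise_level = 0))
  # distal wall moves +38.5 um away; one sample spans 9.625 um two-way
  mid <- ncol(es$rf) %/% 2
  distal <- (mid + 1):ncol(es$rf)
  env1 <- which.max(abs(es$rf[1, distal]))
  env2 <- which.max(abs(es$rf[2, distal]))
  expect_equal(env2 - env1, 4)
  expect_error(
    synthesize_echo_frames(dd, prof,
                           rf_config = list(window_mm = c(10, 16))),
    "imaging window")
})
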