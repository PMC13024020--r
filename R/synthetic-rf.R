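#' Synthesize RF echo frames from a distension waveform
#'
#' Builds an A-mode RF frame sequence consistent with a distension
#' waveform: each frame contains two Gaussian-enveloped tone-burst wall
#' echoes whose round-trip delays follow the wall depths
#' `d_p(t) = wall_depth_prox - dd(t)/2` and
#' `d_d(t) = wall_depth_dist + dd(t)/2` (the distension is split
#' symmetrically across the walls), plus static tissue speckle (seeded
#' scatterers convolved with the pulse) and white noise. Wall echo
#' amplitude is kept at least 5x the scatterer amplitude.
#'
#' @param distension a `"distension_waveform"` (micrometres).
#' @param profile a `"subject_profile"` providing wall depths and the
#'   default noise level.
#' @param rf_config list overriding acquisition parameters: `fs_rf` (Hz,
#'   default 80 MHz), `f0` (transducer centre frequency, default 5 MHz),
#'   `c` (m/s), `pulse_sigma_s` (Gaussian envelope SD, s),
#'   `window_mm` (imaging window, default c(10, 28)), `wall_amp`,
#'   `n_scatterers`, `noise_level` (speckle amplitude relative to the wall
#'   echo; 0 disables speckle and noise), `snr_db` (white-noise SNR
#'   relative to the wall echo peak; `NULL` uses `noise_level / 2`).
#' @param seed integer seed for speckle and noise.
#' @return An [echo_sequence()] with one frame per distension sample.
#' @export
synthesize_echo_frames <- function(distension, profile, rf_config = list(),
                                   seed = 1) {
  stopifnot(inherits(distension, "distension_waveform"))
  cfg <- utils::modifyList(
    list(fs_rf = 80e6, f0 = 5e6, c = 1540, pulse_sigma_s = 8e-8,
         window_mm = c(10, 28), wall_amp = 1, n_scatterers = 120,
         noise_level = profile$noise_level, snr_db = NULL), rf_config)
  if (cfg$fs_rf < 4 * cfg$f0)
    stop_arg("fs_rf must be >= 4 x the transducer centre frequency")
  dd_mm <- distension$dd / 1e3
  d_p <- profile$wall_depth_prox - dd_mm / 2
  d_d <- profile$wall_depth_dist + dd_mm / 2
  span <- cfg$c / (2 * cfg$fs_rf) * 1e3  # mm per sample, two-way
  n_samp <- floor((cfg$window_mm[2] - cfg$window_mm[1]) / span)
  margin <- 1  # mm clearance for the echo footprint
  if (min(d_p) - margin < cfg$window_mm[1] ||
      max(d_d) + margin > cfg$window_mm[2])
    stop_arg("wall depths fall outside the imaging window")

  K <- length(dd_mm)
  rf <- matrix(0, K, n_samp)
  sig_samp <- cfg$pulse_sigma_s * cfg$fs_rf
  L <- ceiling(8 * sig_samp)
  off <- -L:L
  add_wall <- function(depth_mm) {
    pos <- (depth_mm - cfg$window_mm[1]) / span + 1  # fractional sample
    M <- outer(round(pos), off, "+")
    rel <- M - pos  # samples from echo centre
    contrib <- cfg$wall_amp * cos(2 * pi * cfg$f0 * rel / cfg$fs_rf) *
      exp(-rel^2 / (2 * sig_samp^2))
    idx <- cbind(as.vector(row(M)), as.vector(M))
    ok <- idx[, 2] >= 1 & idx[, 2] <= n_samp
    rf[idx[ok, , drop = FALSE]] <<- rf[idx[ok, , drop = FALSE]] +
      as.vector(contrib)[ok]
  }
  add_wall(d_p)
  add_wall(d_d)

  if (cfg$noise_level > 0) {
    set.seed(seed)
    sc_amp <- cfg$wall_amp * min(cfg$noise_level, 0.2)
    bg <- numeric(n_samp)
    # static scatterers model extra-arterial tissue only: the lumen gives
    # no stationary echo (blood speckle decorrelates) and periarterial
    # tissue inside the pulsation zone moves with the wall
    excl <- c((min(d_p) - 0.8 - cfg$window_mm[1]) / span + 1,
              (max(d_d) + 0.8 - cfg$window_mm[1]) / span + 1)
    sc_pos <- stats::runif(cfg$n_scatterers, 1, n_samp)
    bad <- sc_pos > excl[1] & sc_pos < excl[2]
    while (any(bad)) {
      sc_pos[bad] <- stats::runif(sum(bad), 1, n_samp)
      bad <- sc_pos > excl[1] & sc_pos < excl[2]
    }
    sc_a <- stats::rnorm(cfg$n_scatterers, 0, sc_amp)
    for (j in seq_len(cfg$n_scatterers)) {
      i0 <- round(sc_pos[j]) + off
      ok <- i0 >= 1 & i0 <= n_samp
      rel <- i0[ok] - sc_pos[j]
      bg[i0[ok]] <- bg[i0[ok]] + sc_a[j] *
        cos(2 * pi * cfg$f0 * rel / cfg$fs_rf) *
        exp(-rel^2 / (2 * sig_samp^2))
    }
    rf <- rf + matrix(bg, K, n_samp, byrow = TRUE)
    wn_sd <- if (!is.null(cfg$snr_db)) {
      cfg$wall_amp * 10^(-cfg$snr_db / 20)
    } else cfg$wall_amp * cfg$noise_level / 2
    if (wn_sd > 0) rf <- rf + matrix(stats::rnorm(K * n_samp, 0, wn_sd),
                                     K, n_samp)
  }
  echo_sequence(rf, fs_rf = cfg$fs_rf, prf = distension$fs, c = cfg$c,
                z0_mm = cfg$window_mm[1])
}
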