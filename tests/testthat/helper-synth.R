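# Shared fixtures, built lazily and memoised for the session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env))
    assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# One canonical subject profile.
test_profile <- function() {
  fixture("profile", function() make_cohort(1, 7)[[1]])
}

# Clean (jitter-free) 12 s baseline segment with annotations + derivatives.
test_segment <- function() {
  fixture("segment", function() {
    prof <- test_profile()
    dw <- synthesize_distension_segment(prof, prof$baseline_sbp, 60,
                                        12, 200, seed = 1, jitter = 0)
    der <- pulse_derivatives(dw$dd, 200)
    list(prof = prof, dw = dw, der = der,
         beats = segment_beats(der))
  })
}

# Three-subject study under the default synthetic conditions.
small_study <- function() {
  fixture("small_study", function() {
    ds <- generate_dataset(make_cohort(3, 7), master_seed = 42)
    ft <- build_feature_table(ds)
    list(ds = ds, ft = ft,
         study = run_study(ft, seed = 42, cv_folds = 3,
                           max_features = 8))
  })
}

# A synthetic single RF frame with two wall echoes at known depths (mm).
synth_frame_pair <- function(depth1 = 15, depth2 = 23, shift_samples = 0,
                             fs_rf = 80e6, n = 1870, z0_mm = 10,
                             f0 = 5e6, sigma_s = 8e-8) {
  span <- 1540 / (2 * fs_rf) * 1e3
  mk <- function(offset) {
    x <- numeric(n)
    for (d in c(depth1, depth2)) {
      pos <- (d - z0_mm) / span + 1 + offset
      i <- round(pos) + (-60:60)
      ok <- i >= 1 & i <= n
      rel <- i[ok] - pos
      x[i[ok]] <- x[i[ok]] + cos(2 * pi * f0 * rel / fs_rf) *
        exp(-rel^2 / (2 * (sigma_s * fs_rf)^2))
    }
    x
  }
  list(ref = mk(0), nxt = mk(shift_samples))
}
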