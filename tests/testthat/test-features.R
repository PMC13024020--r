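# annotation/derivative pair for one clean beat of the shared segment
clean_beat <- function(k = 3) {
  seg <- test_segment()
  list(ann = locate_fiducials(seg$der, seg$beats$f1[k], seg$beats$f2[k]),
       der = seg$der)
}

test_that("the registry has 52 features partitioned 25/21/2/4", {
  reg <- feature_registry()
  expect_identical(nrow(reg), 52L)
  tally <- feature_count_check(reg)
  expect_identical(unname(tally), c(25L, 21L, 2L, 4L))
  expect_identical(sum(tally), 52L)
  expect_error(feature_count_check(reg[-10, ]), "integrity")
})

test_that("feature vectors carry all 52 named slots", {
  cb <- clean_beat()
  fv <- extract_beat_features(cb$ann, cb$der, height = 1.75)
  expect_length(fv, 52)
  expect_identical(names(fv), feature_registry()$name)
})

test_that("timing features follow their definitions", {
  cb <- clean_beat()
  fv <- extract_beat_features(cb$ann, cb$der, height = 1.75)
  T <- (cb$ann$f2 - cb$ann$f1) / 200
  expect_equal(fv[["T"]], T)
  expect_equal(fv[["IHR"]], 60 / T)
  expect_equal(fv[["prop_s"]], fv[["tsys"]] / T)
  expect_equal(fv[["SI"]], fv[["tsys"]] / 1.75)
  expect_equal(fv[["dT"]], fv[["tDN"]] - fv[["tsys"]])
  expect_equal(fv[["Tdia"]], T - fv[["tDN"]])
  expect_equal(fv[["Tratio"]], fv[["tDN"]] / fv[["Tdia"]])
  expect_equal(fv[["Tb_c"]], fv[["t_c"]] - fv[["t_b"]])
  expect_equal(fv[["IPAD"]], fv[["IPA"]] + fv[["d_div_a"]])
})

test_that("a constructed beat reproduces the worked amplitude examples", {
  # build an exact 1 s beat at 200 Hz where the fiducial amplitudes are
  # dictated, then check AIx, IPA and company against hand arithmetic
  seg <- test_segment()
  der <- seg$der
  ann <- locate_fiducials(der, seg$beats$f1[3], seg$beats$f2[3])
  w <- der$dd_f[ann$f1:ann$f2]
  base <- min(w); amp <- max(w) - base
  fv <- extract_beat_features(ann, der, height = 1.75)
  a_p1in <- der$dd_f[ann$p1in] - base
  a_p2pk <- der$dd_f[ann$p2pk] - base
  expect_equal(fv[["AIx"]], 100 * (a_p2pk - a_p1in) / amp)
  expect_equal(fv[["STT"]], amp / fv[["tsys"]])
  expect_equal(fv[["RI"]], (der$dd_f[ann$DP] - base) / amp)
  expect_equal(fv[["ratio_p2_p1"]],
               (der$dd_f[ann$p2] - base) / (der$dd_f[ann$p1] - base))
  # areas: trapezoids of the baseline-corrected beat on both notch sides
  dt <- 1 / 200
  seg1 <- w[1:(ann$DN - ann$f1 + 1)] - base
  A1 <- dt * sum((seg1[-1] + seg1[-length(seg1)]) / 2)
  expect_equal(fv[["A1"]], A1)
  expect_equal(fv[["IPA"]], fv[["A2"]] / fv[["A1"]])
  # second-derivative amplitude ratios read on d2
  expect_equal(fv[["b_div_a"]], der$d2[ann$b] / der$d2[ann$a])
  expect_equal(fv[["AGI_inf"]],
               (der$d2[ann$b] - der$d2[ann$e]) / der$d2[ann$a])
  # the two slope features: one as printed, one honoring its name
  expect_equal(fv[["slope_b_c"]],
               (der$d2[ann$d] - der$d2[ann$b]) /
                 (fv[["t_c"]] - fv[["t_d"]]))
  expect_equal(fv[["slope_b_d"]],
               (der$d2[ann$d] - der$d2[ann$b]) /
                 (fv[["t_d"]] - fv[["t_b"]]))
})

test_that("absent fiducials yield absent features, never zero", {
  cb <- clean_beat()
  ann <- cb$ann
  ann$DN <- NA_integer_; ann$DP <- NA_integer_
  fv <- extract_beat_features(ann, cb$der, height = 1.75)
  expect_true(all(is.na(fv[c("tDN", "dT", "Tdia", "Tratio", "A1", "A2",
                             "IPA", "RI")])))
  expect_false(anyNA(fv[c("T", "IHR", "tsys", "STT")]))
})

test_that("features are invariant to time shift and scale as documented", {
  seg <- test_segment()
  der <- seg$der
  ann <- locate_fiducials(der, seg$beats$f1[3], seg$beats$f2[3])
  fv <- extract_beat_features(ann, der, height = 1.75)

  # time shift: same beat later in the record
  ann2 <- locate_fiducials(der, seg$beats$f1[6], seg$beats$f2[6])
  fv2 <- extract_beat_features(ann2, der, height = 1.75)
  expect_equal(unname(fv), unname(fv2), tolerance = 1e-9)

  # amplitude scale alpha: ratios unchanged, STT and areas scale
  alpha <- 2.5
  der_s <- pulse_derivatives(der$dd_f * alpha, der$fs)
  ann_s <- locate_fiducials(der_s, seg$beats$f1[3], seg$beats$f2[3])
  fv_s <- extract_beat_features(ann_s, der_s, height = 1.75)
  ratio_feats <- c("amp_p1", "amp_p2", "AIx", "RI", "prop_s", "IPA",
                   "b_div_a", "AGI", "a_div_amp", "ratio_p2_p1")
  expect_equal(fv_s[ratio_feats], fv[ratio_feats], tolerance = 1e-9)
  expect_equal(fv_s[["STT"]], alpha * fv[["STT"]], tolerance = 1e-9)
  expect_equal(fv_s[["A1"]], alpha * fv[["A1"]], tolerance = 1e-9)
})

test_that("generator-derived features match the construction", {
  seg <- test_segment()
  truth <- seg$dw$annotations
  for (k in c(3, 6, 9)) {
    ann <- locate_fiducials(seg$der, seg$beats$f1[k], seg$beats$f2[k])
    fv <- extract_beat_features(ann, seg$der, height = 1.75)
    j <- which(truth$onset_i == seg$beats$f1[k])
    expect_lt(abs(fv[["T"]] - truth$period_T[j]), 1.5 / 200)
    expect_lt(abs(fv[["tsys"]] - (truth$peak_t[j] - truth$onset_t[j])),
              1.5 / 200)
    expect_lt(abs(fv[["IHR"]] - 60 / truth$period_T[j]), 1)
  }
})

test_that("record aggregation is a robust per-feature median", {
  m <- rbind(c(1, 5), c(2, NA), c(100, 6))
  colnames(m) <- c("x", "y")
  ag <- aggregate_record(m)
  expect_equal(unname(ag["x"]), 2)       # outlier-robust
  expect_equal(unname(ag["y"]), 5.5)     # NA ignored (2/3 present)
  m2 <- rbind(c(1, NA), c(2, NA), c(3, 7))
  expect_true(is.na(aggregate_record(m2)["y"]))  # < 50% present
  one <- rbind(c(1, 2), c(1, 2))
  expect_error(aggregate_record(one), "3 valid beats")

  cb <- clean_beat()
  fv <- extract_beat_features(cb$ann, cb$der, height = 1.75)
  same <- rbind(fv, fv, fv)
  expect_equal(aggregate_record(same), fv)
})

test_that("record-level extraction returns one 52-vector per record", {
  dw <- test_segment()$dw
  fv <- extract_record_features(dw, height = 1.7, bandpass = FALSE)
  expect_length(fv, 52)
  expect_gte(attr(fv, "n_beats"), 8)
  expect_false(anyNA(fv[c("T", "tsys", "prop_s", "IHR", "AIx")]))
})
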