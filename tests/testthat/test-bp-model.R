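# small synthetic regression table: tsys drives the target, the rest is
# noise; names drawn from the canonical registry
model_table <- function(n = 40, seed = 1, sd_noise = 0.1,
                        n_noise = 10) {
  set.seed(seed)
  feats <- c("tsys", head(setdiff(feature_registry()$name, "tsys"),
                          n_noise))
  X <- matrix(rnorm(n * (n_noise + 1)), n)
  colnames(X) <- feats
  df <- data.frame(X, check.names = FALSE)
  df$sbp_mmhg <- 120 + 2 * df$tsys + rnorm(n, 0, sd_noise)
  df
}

test_that("the mean-value model predicts the training mean exactly", {
  df <- data.frame(sbp_mmhg = c(120, 130, 125), x = 1:3)
  m <- bp_model(sbp_mmhg ~ x, df, method = "mvm")
  expect_equal(predict(m, data.frame(x = c(9, -4))), c(125, 125))
})

test_that("MLR recovers noiseless linear coefficients to 1e-6", {
  set.seed(3)
  df <- data.frame(prop_s = runif(30))
  df$sbp_mmhg <- 3 + 2 * df$prop_s
  m <- bp_model(sbp_mmhg ~ prop_s, df, method = "mlr")
  expect_equal(unname(coef(m)), c(3, 2), tolerance = 1e-6)
  new <- data.frame(prop_s = c(0.1, 0.9))
  expect_equal(predict(m, new), 3 + 2 * new$prop_s, tolerance = 1e-6)
  expect_lt(max(abs(residuals(m))), 1e-9)
})

test_that("tree models handle a constant target", {
  set.seed(4)
  df <- data.frame(tsys = rnorm(25), sbp_mmhg = 118)
  for (meth in c("rf", "xgb", "mvm")) {
    # randomForest warns about regression on a degenerate target
    m <- suppressWarnings(
      bp_model(sbp_mmhg ~ tsys, df, method = meth, seed = 2))
    expect_equal(predict(m, df), rep(118, 25), tolerance = 1e-6)
  }
})

test_that("fitting guards reject bad inputs", {
  df <- model_table(8)
  expect_error(bp_model(sbp_mmhg ~ ., df, method = "mlr"), "n_features")
  df2 <- model_table(30)
  df2$dup <- df2$tsys
  expect_error(bp_model(sbp_mmhg ~ tsys + dup, df2, method = "mlr"),
               "singular|collinear")
  df3 <- model_table(20)
  df3$tsys[3] <- NA
  expect_error(bp_model(sbp_mmhg ~ tsys, df3, method = "rf"), "impute")
})

test_that("the informative feature ranks first for every method", {
  for (meth in c("rf", "xgb", "mlr")) {
    hits <- vapply(1:5, function(s) {
      df <- model_table(seed = s)
      rank_features(df, method = meth, seed = s)[1]
    }, character(1))
    expect_true(all(hits == "tsys"))
  }
})

test_that("ranking is invariant to feature-column order", {
  df <- model_table(seed = 7)
  feats <- setdiff(names(df), "sbp_mmhg")
  df_perm <- df[, c(rev(feats), "sbp_mmhg")]
  # linear importance is exactly permutation invariant
  r1 <- rank_features(df, feats, method = "mlr", seed = 3)
  r2 <- rank_features(df_perm, rev(feats), method = "mlr", seed = 3)
  expect_identical(r1, r2)
  # the informative feature leads regardless of column order for trees
  r3 <- rank_features(df, feats, method = "rf", seed = 3)
  r4 <- rank_features(df_perm, rev(feats), method = "rf", seed = 3)
  expect_identical(r3[1], r4[1])
  expect_error(
    rank_features(transform(df, sbp_mmhg = 1), method = "rf"),
    "constant")
})

test_that("composite scoring implements the 20-to-1 point rule", {
  feats <- paste0("f", sprintf("%02d", 1:30))
  r1 <- feats
  cs1 <- composite_score(list(r1), top_k = 20)
  expect_equal(cs1$score[cs1$feature == "f01"], 20)
  expect_equal(cs1$score[cs1$feature == "f20"], 1)
  expect_equal(cs1$score[cs1$feature == "f25"], 0)
  expect_equal(sum(cs1$score), 210)

  # two subjects: ranks 1 and 20 sum to 21
  r2 <- c(feats[c(2:20, 1)], feats[21:30])
  cs2 <- composite_score(list(r1, r2), top_k = 20)
  expect_equal(cs2$score[cs2$feature == "f01"], 21)
  expect_equal(sum(cs2$score), 2 * 210)
  expect_true(all(cs2$score <= 2 * 20))
  expect_error(composite_score(list(r1, feats[1:10])), "inconsistent")
})

test_that("selection returns the cross-validated argmin", {
  df <- model_table(n = 45, seed = 11, sd_noise = 1e-8, n_noise = 4)
  cfg <- select_best(df, methods = c("mlr", "rf"), max_features = 4,
                     cv_folds = 3, seed = 2)
  expect_s3_class(cfg, "bp_config")
  # exact linear data: MLR with the informative feature wins
  expect_identical(cfg$method, "mlr")
  expect_identical(cfg$features[1], "tsys")
  expect_equal(cfg$cv_mae, min(cfg$grid$cv_mae))
  # argmin property across the whole grid
  expect_true(all(cfg$cv_mae <= cfg$grid$cv_mae))
})

test_that("evaluation metrics follow their definitions", {
  perfect <- structure(list(method = "mvm", fit = 120, features = character(0),
                            train_y = 120), class = "bp_model")
  ev0 <- evaluate(perfect, data.frame(sbp_mmhg = c(120, 120)))
  expect_equal(ev0$mae, 0)
  expect_equal(ev0$sd_abs_err, 0)

  m <- structure(list(method = "mvm", fit = 0, features = character(0),
                      train_y = 0), class = "bp_model")
  ev <- list(predicted = c(120, 130), observed = c(122, 126))
  ae <- abs(ev$predicted - ev$observed)
  expect_equal(mean(ae), 3)

  set.seed(8)
  df <- data.frame(prop_s = runif(20))
  df$sbp_mmhg <- 3 + 2 * df$prop_s
  mlr <- bp_model(sbp_mmhg ~ prop_s, df, method = "mlr")
  test <- data.frame(prop_s = runif(10))
  test$sbp_mmhg <- 3 + 2 * test$prop_s - 5  # constant offset
  evo <- evaluate(mlr, test)
  expect_equal(evo$mae, 5, tolerance = 1e-6)
  expect_equal(evo$pearson_r, 1, tolerance = 1e-9)
  expect_error(evaluate(mlr, test[0, ]), "empty")
})

test_that("model fitting never touches test rows (no leakage)", {
  df <- model_table(n = 60, seed = 13)
  train <- df[1:40, ]
  cfg1 <- select_best(train, methods = "mlr", max_features = 3,
                      cv_folds = 3, seed = 9)
  m1 <- bp_model(stats::reformulate(cfg1$features, "sbp_mmhg"), train,
                 method = cfg1$method, seed = 1)
  # refit after deleting the held-out rows entirely: identical artifacts
  cfg2 <- select_best(train, methods = "mlr", max_features = 3,
                      cv_folds = 3, seed = 9)
  m2 <- bp_model(stats::reformulate(cfg2$features, "sbp_mmhg"), train,
                 method = cfg2$method, seed = 1)
  expect_identical(cfg1$features, cfg2$features)
  expect_identical(coef(m1), coef(m2))
})
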