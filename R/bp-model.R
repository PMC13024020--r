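#' Fit a personalized SBP calibration model
#'
#' Fits one subject's SBP estimator on training-split feature records.
#' Four methods are supported: `"rf"` (random forest, 500 trees),
#' `"xgb"` (gradient-boosted trees, 300 rounds, eta 0.05, depth 3),
#' `"mlr"` (ordinary least squares) and `"mvm"` (mean-value model - the
#' skill baseline that predicts the training mean regardless of input).
#'
#' @param formula model formula, e.g. `sbp_mmhg ~ .` or an explicit
#'   feature subset.
#' @param data training data frame (one row per record).
#' @param method one of `"rf"`, `"xgb"`, `"mlr"`, `"mvm"`.
#' @param seed integer seed for the stochastic learners.
#' @param ntree random-forest trees. Default 500.
#' @param nrounds,eta,max_depth gradient-boosting hyperparameters.
#' @return An object of class `"bp_model"` with `predict`, `print`,
#'   `summary`, `coef`, `residuals` and `fitted` methods.
#' @export
bp_model <- function(formula, data, method = c("rf", "xgb", "mlr", "mvm"),
                     seed = 1, ntree = 500, nrounds = 300, eta = 0.05,
                     max_depth = 3) {
  method <- match.arg(method)
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  feats <- attr(stats::terms(mf), "term.labels")
  X <- as.matrix(mf[, feats, drop = FALSE])
  if (anyNA(X) && method != "mvm")
    stop_arg("missing feature values: impute before fitting")
  fit <- NULL
  if (method == "mvm") {
    fit <- mean(y)
  } else if (method == "mlr") {
    if (nrow(X) < ncol(X) + 2)
      stop_arg("MLR needs n >= n_features + 2")
    df <- data.frame(.y = y, X, check.names = TRUE)
    fit <- stats::lm(.y ~ ., data = df)
    if (anyNA(stats::coef(fit)))
      stop_arg("MLR fitting error: singular design (collinear features: %s)",
               paste(names(which(is.na(stats::coef(fit)))), collapse = ", "))
  } else if (method == "rf") {
    set.seed(seed)
    fit <- randomForest::randomForest(X, y, ntree = ntree)
  } else {
    set.seed(seed)
    fit <- xgboost::xgboost(
      x = X, y = y, objective = "reg:squarederror", nrounds = nrounds,
      learning_rate = eta, max_depth = max_depth, nthreads = 1,
      seed = seed, verbosity = 0)
  }
  structure(list(method = method, features = feats, fit = fit,
                 train_y = y, train_X = X, seed = seed,
                 call = match.call()),
            class = "bp_model")
}

#' @export
predict.bp_model <- function(object, newdata, ...) {
  if (object$method == "mvm")
    return(rep(object$fit, nrow(newdata)))
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  if (anyNA(X)) stop_arg("missing feature values in newdata")
  switch(object$method,
         mlr = {
           df <- data.frame(X, check.names = TRUE)
           unname(stats::predict(object$fit, newdata = df))
         },
         rf = unname(stats::predict(object$fit, X)),
         xgb = as.numeric(stats::predict(object$fit, X)))
}

#' @export
print.bp_model <- function(x, ...) {
  cat(sprintf("<bp_model> method = %s, %d features, n_train = %d\n",
              x$method, length(x$features), length(x$train_y)))
  invisible(x)
}

#' @export
coef.bp_model <- function(object, ...) {
  if (object$method != "mlr")
    stop_arg("coefficients are only defined for the MLR method")
  stats::coef(object$fit)
}

#' @export
fitted.bp_model <- function(object, ...) {
  predict(object, as.data.frame(object$train_X))
}

#' @export
residuals.bp_model <- function(object, ...) {
  if (object$method == "mlr") unname(stats::residuals(object$fit))
  else object$train_y - fitted(object)
}

#' @export
summary.bp_model <- function(object, ...) {
  res <- residuals(object)
  cat(sprintf(
    "<bp_model> %s | train MAE %.2f mmHg (n = %d, %d features)\n",
    object$method, mean(abs(res)), length(object$train_y),
    length(object$features)))
  invisible(object)
}

#' Rank all features by importance for one subject
#'
#' Model-specific importance on the training split: random forest and
#' gradient boosting use their internal importance (node-purity gain);
#' MLR uses absolute standardized coefficients. Returns a full ordering
#' of every feature (ties, zero-importance and constant features are
#' ordered alphabetically at their score level).
#'
#' @param data training data frame.
#' @param features character vector of feature columns (default: the
#'   canonical 52 present in `data`).
#' @param response response column name. Default `"sbp_mmhg"`.
#' @param method `"rf"`, `"xgb"` or `"mlr"`.
#' @param seed integer seed.
#' @return Character vector: feature names, most important first.
#' @export
rank_features <- function(data, features = NULL, response = "sbp_mmhg",
                          method = c("rf", "xgb", "mlr"), seed = 1) {
  method <- match.arg(method)
  if (is.null(features))
    features <- intersect(feature_registry()$name, names(data))
  y <- data[[response]]
  if (length(unique(y)) < 2) stop_arg("ranking error: constant target")
  X <- as.matrix(data[, features, drop = FALSE])
  if (anyNA(X)) stop_arg("missing feature values: impute before ranking")
  score <- stats::setNames(numeric(length(features)), features)
  if (method == "rf") {
    set.seed(seed)
    rf <- randomForest::randomForest(X, y, ntree = 500, importance = FALSE)
    imp <- randomForest::importance(rf)[, 1]
    score[names(imp)] <- imp
  } else if (method == "xgb") {
    set.seed(seed)
    bst <- xgboost::xgboost(
      x = X, y = y, objective = "reg:squarederror", nrounds = 300,
      learning_rate = 0.05, max_depth = 3, nthreads = 1, seed = seed,
      verbosity = 0)
    imp <- xgboost::xgb.importance(model = bst)
    score[imp$Feature] <- imp$Gain
  } else {
    sds <- apply(X, 2, stats::sd)
    ok <- sds > 0
    Xs <- scale(X[, ok, drop = FALSE])
    df <- data.frame(.y = y, Xs, check.names = FALSE)
    co <- stats::coef(stats::lm(.y ~ ., data = df))[-1]
    co[is.na(co)] <- 0
    score[names(co)] <- abs(co)
  }
  features[order(-score, features)]
}

#' Composite cross-subject feature scoring
#'
#' For each subject's ranking, the feature ranked r in the top
#' `top_k` contributes `top_k + 1 - r` points (20 down to 1 by default);
#' features outside the top `top_k` contribute 0. Points are summed over
#' subjects and features ranked by descending composite score (ties
#' alphabetical).
#'
#' @param rankings list of per-subject orderings (character vectors over
#'   an identical feature set).
#' @param top_k depth of the per-subject selection. Default 20.
#' @return Data frame `feature`, `score`, `rank`, ordered by rank.
#' @export
composite_score <- function(rankings, top_k = 20) {
  if (!length(rankings)) stop_arg("no rankings given")
  ref <- sort(rankings[[1]])
  for (r in rankings)
    if (!identical(sort(r), ref))
      stop_arg("rankings cover inconsistent feature sets")
  score <- stats::setNames(numeric(length(ref)), ref)
  for (r in rankings) {
    top <- utils::head(r, top_k)
    score[top] <- score[top] + (top_k + 1 - seq_along(top))
  }
  ord <- order(-score, names(score))
  data.frame(feature = names(score)[ord], score = unname(score[ord]),
             rank = seq_along(score), row.names = NULL)
}

#' Select the best model configuration by cross-validation
#'
#' Grid search over method x number of top-ranked features, scored by
#' k-fold cross-validated MAE on the training split only. Ties prefer
#' fewer features, then the simpler method (mlr < rf < xgb).
#'
#' @param data training data frame (imputed).
#' @param response response column. Default `"sbp_mmhg"`.
#' @param methods candidate methods. Default `c("mlr", "rf", "xgb")`.
#' @param max_features top-n grid upper bound. Default 20.
#' @param cv_folds folds. Default 5.
#' @param seed integer seed (fold assignment and learners).
#' @return List of class `"bp_config"`: `method`, `n_features`,
#'   `features` (ordered), `cv_mae`, `seed`, plus the full `grid` of
#'   candidate scores.
#' @export
select_best <- function(data, response = "sbp_mmhg",
                        methods = c("mlr", "rf", "xgb"),
                        max_features = 20, cv_folds = 5, seed = 1) {
  n <- nrow(data)
  if (n < cv_folds * 3) stop_arg("need at least %d training records",
                                 cv_folds * 3)
  feats_all <- intersect(feature_registry()$name, names(data))
  set.seed(fanout_seed(seed, 1))
  fold <- sample(rep(seq_len(cv_folds), length.out = n))
  grid <- list()
  method_prio <- c(mlr = 1, rf = 2, xgb = 3)
  for (m in methods) {
    ranking <- rank_features(data, feats_all, response, m,
                             seed = fanout_seed(seed, 2))
    for (nf in seq_len(min(max_features, length(ranking)))) {
      fsub <- ranking[seq_len(nf)]
      errs <- numeric(0)
      ok <- TRUE
      for (f in seq_len(cv_folds)) {
        tr <- data[fold != f, , drop = FALSE]
        te <- data[fold == f, , drop = FALSE]
        fml <- stats::reformulate(fsub, response)
        fit <- try(bp_model(fml, tr, method = m,
                            seed = fanout_seed(seed, 100 + f)),
                   silent = TRUE)
        if (inherits(fit, "try-error")) { ok <- FALSE; break }
        errs <- c(errs, abs(predict(fit, te) - te[[response]]))
      }
      if (!ok) next
      grid[[length(grid) + 1]] <- data.frame(
        method = m, n_features = nf, cv_mae = mean(errs),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(grid)) stop_arg("selection error: every candidate failed")
  g <- do.call(rbind, grid)
  ord <- order(g$cv_mae, g$n_features, method_prio[g$method])
  best <- g[ord[1], ]
  ranking <- rank_features(data, feats_all, response, best$method,
                           seed = fanout_seed(seed, 2))
  structure(list(method = best$method, n_features = best$n_features,
                 features = ranking[seq_len(best$n_features)],
                 cv_mae = best$cv_mae, seed = seed, grid = g),
            class = "bp_config")
}

#' @export
print.bp_config <- function(x, ...) {
  cat(sprintf("<bp_config> %s with %d features (CV MAE %.2f mmHg)\n",
              x$method, x$n_features, x$cv_mae))
  invisible(x)
}

#' Evaluate a fitted model on test records
#'
#' @param model a `"bp_model"`.
#' @param test test data frame with the response column.
#' @param response response column. Default `"sbp_mmhg"`.
#' @return List of class `"bp_eval"`: `mae` (mean absolute error, mmHg),
#'   `sd_abs_err` (SD of the absolute errors), `pearson_r` (NA when
#'   undefined), `n`, `residuals`, `predicted`, `observed`.
#' @export
evaluate <- function(model, test, response = "sbp_mmhg") {
  if (!nrow(test)) stop_arg("empty test set")
  yhat <- predict(model, test)
  y <- test[[response]]
  ae <- abs(yhat - y)
  r <- if (stats::sd(yhat) > 0 && stats::sd(y) > 0)
    stats::cor(yhat, y) else NA_real_
  structure(list(mae = mean(ae), sd_abs_err = stats::sd(ae),
                 pearson_r = r, n = length(y),
                 residuals = yhat - y, predicted = yhat, observed = y),
            class = "bp_eval")
}

#' @export
print.bp_eval <- function(x, ...) {
  cat(sprintf("<bp_eval> MAE %.2f +/- %.2f mmHg, r = %s, n = %d\n",
              x$mae, x$sd_abs_err,
              if (is.na(x$pearson_r)) "NA" else sprintf("%.2f", x$pearson_r),
              x$n))
  invisible(x)
}
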