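# Training-median imputation: medians learned on the training split only.
impute_by_train <- function(train, others, features) {
  med <- vapply(features, function(f) {
    v <- train[[f]]
    if (all(!is.finite(v))) NA_real_ else stats::median(v[is.finite(v)])
  }, numeric(1))
  usable <- names(med)[is.finite(med)]
  fill <- function(df) {
    for (f in usable) {
      v <- df[[f]]
      v[!is.finite(v)] <- med[[f]]
      df[[f]] <- v
    }
    df
  }
  list(train = fill(train), others = lapply(others, fill),
       features = usable)
}

#' Run the full per-subject calibration study
#'
#' For every subject: impute missing feature values by training-split
#' medians, select the best method x feature-count configuration by
#' cross-validation on the training split, refit on the full training
#' split, and evaluate on the short-term (group 3) and long-term
#' (group 4) test splits alongside the mean-value baseline. Also computes
#' the cross-subject composite feature ranking per method and pooled
#' (record-weighted) test metrics.
#'
#' @param features_df record-level feature table (see
#'   [build_feature_table()]), with columns `subject_id`, `split`,
#'   `sbp_mmhg` and the canonical features.
#' @param methods candidate methods. Default `c("mlr", "rf", "xgb")`.
#' @param max_features top-n grid bound. Default 20.
#' @param cv_folds CV folds for selection. Default 5.
#' @param seed master seed.
#' @param fixed_config optional list(method=, n_features=) to skip
#'   selection and fit one fixed configuration per subject.
#' @return An object of class `"bp_study"`: `subjects` (per-subject
#'   configs and evaluations), `pooled` (record-weighted best-model and
#'   baseline metrics per split), `composite` (per-method composite
#'   feature rankings), `seed`.
#' @export
run_study <- function(features_df, methods = c("mlr", "rf", "xgb"),
                      max_features = 20, cv_folds = 5, seed = 42,
                      fixed_config = NULL) {
  feats_all <- intersect(feature_registry()$name, names(features_df))
  subjects <- unique(features_df$subject_id)
  per_subject <- list()
  rankings <- stats::setNames(
    lapply(methods, function(m) list()), methods)
  skipped <- character(0)
  for (sid in subjects) {
    sub <- features_df[features_df$subject_id == sid, , drop = FALSE]
    train <- sub[sub$split == "train", , drop = FALSE]
    short <- sub[sub$split == "short_term", , drop = FALSE]
    long <- sub[sub$split == "long_term", , drop = FALSE]
    if (!nrow(train) || !nrow(short)) {
      warning(sprintf("subject %s skipped: missing train or short_term",
                      sid))
      skipped <- c(skipped, sid)
      next
    }
    s_seed <- fanout_seed(seed, match(sid, subjects))
    imp <- impute_by_train(train, list(short = short, long = long),
                           feats_all)
    train_i <- imp$train
    short_i <- imp$others$short
    long_i <- imp$others$long
    usable <- imp$features

    for (m in methods) {
      rankings[[m]][[sid]] <- rank_features(
        train_i, usable, method = m, seed = fanout_seed(s_seed, 2))
    }

    cfg <- if (is.null(fixed_config)) {
      select_best(train_i[, c("sbp_mmhg", usable)], methods = methods,
                  max_features = min(max_features, length(usable)),
                  cv_folds = cv_folds, seed = s_seed)
    } else {
      rk <- rank_features(train_i, usable,
                          method = fixed_config$method,
                          seed = fanout_seed(s_seed, 2))
      nf <- min(fixed_config$n_features, length(rk))
      structure(list(method = fixed_config$method, n_features = nf,
                     features = rk[seq_len(nf)], cv_mae = NA_real_,
                     seed = s_seed, grid = NULL), class = "bp_config")
    }
    fml <- stats::reformulate(cfg$features, "sbp_mmhg")
    best <- bp_model(fml, train_i, method = cfg$method,
                     seed = fanout_seed(s_seed, 3))
    mvm <- bp_model(sbp_mmhg ~ 1, train_i, method = "mvm")
    per_subject[[sid]] <- list(
      subject_id = sid, config = cfg,
      n_train = nrow(train_i),
      eval_short = evaluate(best, short_i),
      eval_long = if (nrow(long_i)) evaluate(best, long_i) else NULL,
      mvm_short = evaluate(mvm, short_i),
      mvm_long = if (nrow(long_i)) evaluate(mvm, long_i) else NULL)
  }
  if (!length(per_subject)) stop_arg("no subject could be evaluated")

  pool <- function(field) {
    evs <- Filter(Negate(is.null), lapply(per_subject, `[[`, field))
    if (!length(evs)) return(NULL)
    yhat <- unlist(lapply(evs, `[[`, "predicted"))
    y <- unlist(lapply(evs, `[[`, "observed"))
    ae <- abs(yhat - y)
    list(mae = mean(ae), sd_abs_err = stats::sd(ae),
         pearson_r = if (stats::sd(yhat) > 0 && stats::sd(y) > 0)
           stats::cor(yhat, y) else NA_real_,
         n = length(y))
  }
  composite <- lapply(rankings, function(rl)
    if (length(rl)) composite_score(unname(rl), top_k = 20) else NULL)

  structure(list(
    subjects = per_subject,
    pooled = list(best_short = pool("eval_short"),
                  best_long = pool("eval_long"),
                  mvm_short = pool("mvm_short"),
                  mvm_long = pool("mvm_long")),
    composite = composite, seed = seed, skipped = skipped),
    class = "bp_study")
}

#' @export
print.bp_study <- function(x, ...) {
  cat(sprintf("<bp_study> %d subjects (seed %d)\n",
              length(x$subjects), x$seed))
  fmt <- function(p) if (is.null(p)) "  -" else
    sprintf("MAE %5.2f +/- %5.2f mmHg, r = %s, n = %d",
            p$mae, p$sd_abs_err,
            if (is.na(p$pearson_r)) "NA" else sprintf("%.2f", p$pearson_r),
            p$n)
  cat("  best model, short-term: ", fmt(x$pooled$best_short), "\n")
  cat("  best model, long-term:  ", fmt(x$pooled$best_long), "\n")
  cat("  MVM baseline, short:    ", fmt(x$pooled$mvm_short), "\n")
  cat("  MVM baseline, long:     ", fmt(x$pooled$mvm_long), "\n")
  invisible(x)
}

#' @export
summary.bp_study <- function(object, ...) {
  print(object)
  cat("\nPer-subject best configurations:\n")
  for (s in object$subjects) {
    cat(sprintf("  %s: %s / %2d features | short MAE %5.2f%s\n",
                s$subject_id, s$config$method, s$config$n_features,
                s$eval_short$mae,
                if (!is.null(s$eval_long))
                  sprintf(", long MAE %5.2f", s$eval_long$mae) else ""))
  }
  invisible(object)
}
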