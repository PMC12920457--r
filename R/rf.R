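#' Configuration for random-forest calibration
#'
#' @param n_trees Number of trees (default 200).
#' @param min_leaf Minimum terminal-node size (default 10).
#' @param tuning_iterations Number of candidate hyperparameter settings
#'   evaluated by seeded random search (default 50); 0 disables tuning and
#'   fits with `mtry_fraction = 1/3` and `min_leaf` as given.
#' @param cv_folds Cross-validation folds used as the tuning objective
#'   (default 5); the objective is the mean CV RMSE.
#' @param mtry_fraction_range Search range for the per-split feature
#'   fraction (default c(0.1, 1)).
#' @param min_leaf_range Search range for `min_leaf` when `tune_min_leaf`
#'   is TRUE (default c(5, 15)).
#' @param tune_min_leaf Also search the leaf size around its default
#'   (default FALSE: leaf size stays fixed as printed).
#' @param seed RNG seed for candidate draws, fold assignment and tree
#'   growing.
#' @return An object of class `rf_config`.
#' @export
rf_config <- function(n_trees = 200,
                      min_leaf = 10,
                      tuning_iterations = 50,
                      cv_folds = 5,
                      mtry_fraction_range = c(0.1, 1),
                      min_leaf_range = c(5, 15),
                      tune_min_leaf = FALSE,
                      seed = 1L) {
  if (n_trees < 1 || min_leaf < 1 || cv_folds < 2) {
    stopf("n_trees, min_leaf must be positive and cv_folds >= 2")
  }
  structure(list(
    n_trees = as.integer(n_trees),
    min_leaf = as.integer(min_leaf),
    tuning_iterations = as.integer(tuning_iterations),
    cv_folds = as.integer(cv_folds),
    mtry_fraction_range = mtry_fraction_range,
    min_leaf_range = min_leaf_range,
    tune_min_leaf = isTRUE(tune_min_leaf),
    seed = as.integer(seed)
  ), class = "rf_config")
}

rf_one_fit <- function(X, y, cfg, mtry_frac, min_leaf, seed) {
  mtry <- max(1L, min(ncol(X), round(mtry_frac * ncol(X))))
  with_seed(seed, randomForest::randomForest(
    x = X, y = y, ntree = cfg$n_trees, mtry = mtry,
    nodesize = min_leaf))
}

#' Fit a random-forest calibration model
#'
#' Grows a bagged ensemble of regression trees with the configured tree
#' count and leaf size.  When `tuning_iterations > 0`, a seeded random
#' search over the per-split feature fraction (and optionally the leaf
#' size) evaluates each candidate by mean cross-validated RMSE over
#' shuffled folds and refits the best candidate on the full training set.
#'
#' @param X_train Numeric matrix (samples x features).
#' @param y_train Response vector (tannin, mg/g).
#' @param cfg An [rf_config()].
#' @param verbose Message the selected candidate (default FALSE).
#' @return An `rf_model`: list with the fitted forest, the winning
#'   hyperparameters, the tuning trace and a config echo.
#' @export
fit_rf <- function(X_train, y_train, cfg = rf_config(), verbose = FALSE) {
  X_train <- as.matrix(X_train)
  if (any(!is.finite(X_train))) stopf("non-finite feature values")
  n <- nrow(X_train)
  if (n < cfg$cv_folds) stopf("fewer training samples (%d) than folds", n)
  cn <- colnames(X_train)
  if (is.null(cn) || any(cn == "") || anyDuplicated(cn)) {
    colnames(X_train) <- sprintf("f%04d", seq_len(ncol(X_train)))
  }
  trace <- NULL
  best <- list(mtry_frac = 1 / 3, min_leaf = cfg$min_leaf)
  if (cfg$tuning_iterations > 0 && stats::var(y_train) > 0) {
    cand <- with_seed(derive_seed(cfg$seed, 1), data.frame(
      mtry_frac = stats::runif(cfg$tuning_iterations,
                               cfg$mtry_fraction_range[1],
                               cfg$mtry_fraction_range[2]),
      min_leaf = if (cfg$tune_min_leaf) {
        sample(seq(cfg$min_leaf_range[1], cfg$min_leaf_range[2]),
               cfg$tuning_iterations, replace = TRUE)
      } else rep(cfg$min_leaf, cfg$tuning_iterations)
    ))
    folds <- with_seed(derive_seed(cfg$seed, 2),
                       sample(rep(seq_len(cfg$cv_folds), length.out = n)))
    cv_rmse <- vapply(seq_len(cfg$tuning_iterations), function(k) {
      errs <- vapply(seq_len(cfg$cv_folds), function(f) {
        tr <- folds != f
        fit <- rf_one_fit(X_train[tr, , drop = FALSE], y_train[tr], cfg,
                          cand$mtry_frac[k], cand$min_leaf[k],
                          derive_seed(cfg$seed, 100 + k * 10 + f))
        pred <- predict(fit, X_train[!tr, , drop = FALSE])
        sqrt(mean((pred - y_train[!tr])^2))
      }, numeric(1))
      mean(errs)
    }, numeric(1))
    trace <- cbind(cand, cv_rmse = cv_rmse)
    k_best <- which.min(cv_rmse)
    best <- list(mtry_frac = cand$mtry_frac[k_best],
                 min_leaf = cand$min_leaf[k_best])
    msgf(verbose, "tuning winner: mtry_frac=%.3f min_leaf=%d (CV RMSE %.4f)",
         best$mtry_frac, best$min_leaf, cv_rmse[k_best])
  }
  forest <- rf_one_fit(X_train, y_train, cfg, best$mtry_frac,
                       best$min_leaf, derive_seed(cfg$seed, 3))
  structure(list(
    forest = forest,
    mtry_fraction = best$mtry_frac,
    min_leaf = best$min_leaf,
    feature_names = colnames(X_train),
    tuning_trace = trace,
    config = cfg
  ), class = "rf_model")
}

#' @export
predict.rf_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  colnames(newdata) <- object$feature_names
  unname(predict(object$forest, newdata))
}

#' @export
print.rf_model <- function(x, ...) {
  cat(sprintf(
    "rf_model: %d trees, min_leaf %d, mtry_fraction %.3f, %d features\n",
    x$config$n_trees, x$min_leaf, x$mtry_fraction,
    length(x$feature_names)))
  invisible(x)
}

#' Calibration metrics: R2, RMSE, RPD
#'
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`,
#' `RMSE = sqrt(mean((y - yhat)^2))`, and
#' `RPD = sd(y) / RMSE` with the sample SD (n-1 denominator) of the
#' evaluated set's own reference values.  By convention an RPD between
#' 1.4 and 2.0 indicates a moderately reliable calibration and RPD > 2.0
#' a robust one.
#'
#' @param model A fitted model with a `predict` method (e.g. `rf_model`),
#'   or NULL when `predictions` are supplied directly.
#' @param X Feature matrix of the evaluation set (ignored when
#'   `predictions` given).
#' @param y Reference values of the evaluation set.
#' @param predictions Optional pre-computed predictions.
#' @return One-row data frame `R2`, `RMSE`, `RPD`.  A perfect fit yields
#'   `RPD = Inf` with a warning; a constant `y` is an error for RPD.
#' @export
evaluate_calibration <- function(model, X, y, predictions = NULL) {
  if (is.null(predictions)) predictions <- predict(model, X)
  if (length(predictions) != length(y) || length(y) == 0) {
    stopf("evaluation set is empty or misaligned")
  }
  rmse <- sqrt(mean((y - predictions)^2))
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stopf("constant reference values: RPD undefined")
  r2 <- 1 - sum((y - predictions)^2) / ss_tot
  rpd <- if (rmse == 0) {
    warning("zero RMSE: RPD reported as Inf", call. = FALSE)
    Inf
  } else {
    stats::sd(y) / rmse
  }
  data.frame(R2 = r2, RMSE = rmse, RPD = rpd)
}

#' Fit and compare calibration models across input definitions
#'
#' Runs one random-forest calibration per named feature set on a shared
#' train/validation split and tabulates per-set metrics, flagging likely
#' overfitting when the train-validation R2 gap exceeds `overfit_margin`.
#'
#' @param feature_sets Named list of numeric matrices (samples x features),
#'   all with rownames matching the sample ids of `tannins`.  Names encode
#'   the input definition (e.g. `"lg'(1/R)_CWT_256 characteristic"`).
#' @param tannins Reference table (`sample_id`, `tannin`).
#' @param split A `split_result` shared by every run.
#' @param cfg An [rf_config()].
#' @param overfit_margin Allowed train-validation R2 gap (default 0.2).
#' @param verbose Message progress.
#' @return A `model_comparison`: list with `table` (one row per
#'   input x set), `models` (named list of `rf_model`s) and
#'   `predictions` (per input, reference vs predicted per set).
#' @export
compare_inputs <- function(feature_sets, tannins, split,
                           cfg = rf_config(), overfit_margin = 0.2,
                           verbose = FALSE) {
  stopifnot(inherits(split, "split_result"))
  rows <- list()
  models <- list()
  preds <- list()
  for (nm in names(feature_sets)) {
    X <- as.matrix(feature_sets[[nm]])
    if (is.null(rownames(X))) stopf("feature set '%s' lacks rownames", nm)
    tr_idx <- match(split$train_ids, rownames(X))
    va_idx <- match(split$val_ids, rownames(X))
    if (anyNA(tr_idx) || anyNA(va_idx)) {
      stopf("feature set '%s' is missing split sample(s)", nm)
    }
    y_tr <- tannins$tannin[match(split$train_ids, tannins$sample_id)]
    y_va <- tannins$tannin[match(split$val_ids, tannins$sample_id)]
    msgf(verbose, "fitting '%s' (%d features)", nm, ncol(X))
    mod <- fit_rf(X[tr_idx, , drop = FALSE], y_tr, cfg)
    m_tr <- evaluate_calibration(mod, X[tr_idx, , drop = FALSE], y_tr)
    m_va <- evaluate_calibration(mod, X[va_idx, , drop = FALSE], y_va)
    gap <- m_tr$R2 - m_va$R2
    rows[[nm]] <- rbind(
      data.frame(input = nm, set = "train", m_tr,
                 r2_gap = gap, overfit = gap > overfit_margin),
      data.frame(input = nm, set = "validation", m_va,
                 r2_gap = gap, overfit = gap > overfit_margin))
    models[[nm]] <- mod
    preds[[nm]] <- data.frame(
      sample_id = c(split$train_ids, split$val_ids),
      set = rep(c("train", "validation"),
                c(length(tr_idx), length(va_idx))),
      reference = c(y_tr, y_va),
      predicted = c(predict(mod, X[tr_idx, , drop = FALSE]),
                    predict(mod, X[va_idx, , drop = FALSE])))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, models = models, predictions = preds),
            class = "model_comparison")
}
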