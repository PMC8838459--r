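# Calibration of measured PPG beat intensities onto the simulated
# intensity scale with gradient-boosted regression trees, fitted
# separately for the systolic and diastolic branches and validated by
# repeated 10-fold cross-validation.

.calib_features <- c("systolic_intensity", "diastolic_intensity",
                     "skewness", "kurtosis", "BMI", "pulse_rate")

#' Hyperparameters of the calibration ensemble
#'
#' @param nrounds Number of boosting rounds (default 300).
#' @param max_depth Tree depth (default 4).
#' @param eta Learning rate (default 0.05).
#' @param subsample Row subsampling fraction (default 0.9).
#' @return Named list of hyperparameters.
#' @export
calibration_params <- function(nrounds = 300, max_depth = 4, eta = 0.05,
                               subsample = 0.9) {
  list(nrounds = nrounds, max_depth = max_depth, eta = eta,
       subsample = subsample)
}

#' Build a calibration dataset
#'
#' Joins extracted beat features with cohort reference pressures and
#' attaches the regression target: the table intensity interpolated at
#' each subject's reference SBP (systolic branch) or DBP (diastolic
#' branch).  Subjects whose reference pressure falls outside the table
#' range are excluded with a message.
#'
#' @param features Data frame from [extract_cohort_features()].
#' @param refs Data frame with `subject_id`, `SBP`, `DBP`, `BMI`,
#'   `pulse_rate`.
#' @param table A monotone [intensity_table()].
#' @param branch `"systolic"` or `"diastolic"`.
#' @return Object of class `calibration_dataset`: a data frame with the
#'   six feature columns, `target`, and `subject_id`.
#' @export
build_calibration_dataset <- function(features, refs, table,
                                      branch = c("systolic", "diastolic")) {
  branch <- match.arg(branch)
  stopifnot(inherits(table, "intensity_table"))
  df <- merge(features, refs[, c("subject_id", "SBP", "DBP", "BMI",
                                 "pulse_rate")], by = "subject_id")
  ref_p <- if (branch == "systolic") df$SBP else df$DBP
  in_range <- ref_p >= min(table$pressure) & ref_p <= max(table$pressure)
  if (any(!in_range))
    message(sum(!in_range), " subject(s) excluded: reference pressure ",
            "outside the table range")
  df <- df[in_range, , drop = FALSE]
  ref_p <- ref_p[in_range]
  df$target <- interp_intensity(table, ref_p)
  if (anyNA(df[, c(.calib_features, "target")]))
    stop("calibration dataset contains missing values")
  out <- df[, c("subject_id", .calib_features, "target")]
  class(out) <- c("calibration_dataset", "data.frame")
  attr(out, "branch") <- branch
  out
}

#' Fit the gradient-boosted calibration model
#'
#' Fits a gradient-boosted regression-tree ensemble mapping the
#' six-feature vector to the simulated target intensity, and reports the
#' mean cross-validated R-squared over 10-fold cross-validation repeated
#' three times (fold assignments reshuffled each repeat with seeds
#' derived from `seed`; R-squared is the squared Pearson correlation of
#' pooled out-of-fold predictions with the targets).  The returned model
#' is refit on all rows.
#'
#' @param dataset A [build_calibration_dataset()] result (>= 20 rows).
#' @param params [calibration_params()].
#' @param seed Integer seed controlling fold shuffling and ensemble
#'   subsampling.
#' @param folds Number of CV folds (default 10).
#' @param repeats Number of CV repeats (default 3).
#' @return Object of class `calibration_model` with elements `booster`,
#'   `branch`, `cv_r2` (mean), `cv_r2_repeats`, `importance`, `params`,
#'   `seed`.
#' @export
fit_calibration <- function(dataset, params = calibration_params(),
                            seed = 1, folds = 10, repeats = 3) {
  stopifnot(inherits(dataset, "calibration_dataset"))
  if (nrow(dataset) < 20)
    stop("need at least 20 rows to fit the calibration model")
  if (stats::sd(dataset$target) == 0)
    stop("degenerate (constant) calibration target")
  # targets are simulated intensities of magnitude ~1e-4; rescale to O(1)
  # so the ensemble's leaf-weight regularization does not stall the fit
  y_scale <- mean(abs(dataset$target))
  if (y_scale == 0) y_scale <- 1
  y <- dataset$target / y_scale
  X <- as.matrix(dataset[, .calib_features])
  storage.mode(X) <- "double"

  xgb_par <- list(max_depth = params$max_depth, eta = params$eta,
                  subsample = params$subsample,
                  objective = "reg:squarederror", nthread = 1)

  train_once <- function(rows, xgb_seed) {
    dm <- xgboost::xgb.DMatrix(X[rows, , drop = FALSE], label = y[rows])
    xgboost::xgb.train(c(xgb_par, list(seed = xgb_seed)), dm,
                       nrounds = params$nrounds, verbose = 0)
  }

  n <- nrow(X)
  cv_r2_rep <- numeric(repeats)
  for (r in seq_len(repeats)) {
    rep_seed <- seed + 7919 * r
    set.seed(rep_seed)
    fold_id <- sample(rep_len(seq_len(folds), n))
    oof <- numeric(n)
    for (k in seq_len(folds)) {
      test <- which(fold_id == k)
      if (length(test) == 0) next
      fit <- train_once(which(fold_id != k), rep_seed + k)
      oof[test] <- stats::predict(
        fit, xgboost::xgb.DMatrix(X[test, , drop = FALSE]))
    }
    cv_r2_rep[r] <- stats::cor(oof, y)^2
  }

  final <- train_once(seq_len(n), seed)
  imp <- tryCatch(xgboost::xgb.importance(model = final),
                  error = function(e) NULL)
  structure(list(
    booster = final, branch = attr(dataset, "branch"),
    cv_r2 = mean(cv_r2_rep), cv_r2_repeats = cv_r2_rep,
    importance = imp, params = params, seed = seed,
    features = .calib_features, y_scale = y_scale
  ), class = "calibration_model")
}

#' Predict calibrated intensity on the simulation scale
#'
#' @param model A [fit_calibration()] model.
#' @param newdata Data frame containing the model's feature columns.
#' @return Numeric predictions (>= 0; rare negative raw outputs are
#'   clamped to zero and flagged via attribute `clamped`).
#' @export
predict_calibrated_intensity <- function(model, newdata) {
  stopifnot(inherits(model, "calibration_model"))
  miss <- setdiff(model$features, names(newdata))
  if (length(miss) > 0)
    stop("missing calibration features: ", paste(miss, collapse = ", "))
  X <- as.matrix(newdata[, model$features, drop = FALSE])
  storage.mode(X) <- "double"
  p <- stats::predict(model$booster, xgboost::xgb.DMatrix(X)) *
    model$y_scale
  clamped <- p < 0
  p[clamped] <- 0
  attr(p, "clamped") <- clamped
  p
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("calibration_model (%s branch): CV R^2 = %.4f (%s)\n",
              x$branch, x$cv_r2,
              paste(sprintf("%.3f", x$cv_r2_repeats), collapse = ", ")))
  invisible(x)
}
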