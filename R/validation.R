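## Calibration/validation metrics and resampling: RMSE, R-squared,
## leave-one-out cross-validation and 50/50 random holdout.

#' Root mean square error
#'
#' @param observed,predicted Numeric vectors of equal length, mg/kg.
#' @return `sqrt(mean((observed - predicted)^2))`, mg/kg.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 1L) {
    stop_nircal("shape error: lengths %d vs %d", length(observed),
                length(predicted), class = "nircal_shape")
  }
  sqrt(mean((observed - predicted)^2))
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot`, where `SS_tot` is taken about the mean of
#' the observed values. May be negative when the predictions are worse than
#' predicting the observed mean.
#'
#' @param observed,predicted Numeric vectors of equal length; `observed`
#'   must have nonzero variance.
#' @return Dimensionless, at most 1.
#' @export
r2 <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop_nircal("shape error: lengths %d vs %d", length(observed),
                length(predicted), class = "nircal_shape")
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    stop_nircal("undefined variance: observed values are constant",
                class = "nircal_undefined_variance")
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Construct a validation report
#' @noRd
validation_report <- function(rmsec, r2c, rmsev, r2v, observed, predicted,
                              mode, preprocessing = NA_character_,
                              n_components_after_filter = NA_integer_,
                              n_components_after_regression = NA_integer_,
                              extra = list()) {
  structure(c(list(rmsec = rmsec, r2c = r2c, rmsev = rmsev, r2v = r2v,
                   n_components_after_filter = n_components_after_filter,
                   n_components_after_regression = n_components_after_regression,
                   preprocessing = preprocessing, mode = mode,
                   pairs = data.frame(observed = observed,
                                      predicted = predicted)),
              extra),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s / %s\n",
              ifelse(is.na(x$preprocessing), "-", x$preprocessing),
              x$mode))
  cat(sprintf("  RMSEC %8.2f mg/kg   R2c %6.3f\n", x$rmsec, x$r2c))
  cat(sprintf("  RMSEV %8.2f mg/kg   R2v %6.3f\n", x$rmsev, x$r2v))
  invisible(x)
}

#' Leave-one-out cross-validation of a linear calibration
#'
#' Works on a fixed design (the channels selected upstream): for each of
#' the `N` folds the coefficients are refit on the remaining `N - 1`
#' samples and the held-out sample is predicted. RMSEV and validation
#' R-squared summarize the `N` held-out predictions; RMSEC and calibration
#' R-squared come from the full-data fit. For the variant that redoes the
#' channel selection inside each fold, see [run_pipeline()] with
#' `selection_in_fold = TRUE`.
#'
#' @param design `N x m` predictor matrix (selected channels).
#' @param response Concentrations, length `N >= 3`.
#' @return A `validation_report`.
#' @export
loocv <- function(design, response) {
  design <- as.matrix(design)
  n <- length(response)
  if (n < 3L) {
    stop_nircal("need at least 3 samples for LOOCV",
                class = "nircal_invalid_design")
  }
  full <- fit_ols(design, response)
  pred <- vapply(seq_len(n), function(i) {
    fit_i <- tryCatch(
      fit_ols(design[-i, , drop = FALSE], response[-i]),
      error = function(e) {
        stop_nircal("LOOCV fold failed at sample %d: %s", i,
                    conditionMessage(e), class = "nircal_fold_error")
      })
    drop(c(1, design[i, ]) %*% fit_i$coefficients)
  }, numeric(1))
  validation_report(rmsec = rmse(response, full$fitted),
                    r2c = r2(response, full$fitted),
                    rmsev = rmse(response, pred),
                    r2v = r2(response, pred),
                    observed = response, predicted = pred,
                    mode = "loocv",
                    extra = list(n_folds = n))
}

#' Seeded 50/50 (or general-fraction) holdout split
#'
#' Uniform random partition without replacement. `fraction` is the share
#' of samples used for training; with an odd sample count the validation
#' part receives the larger half (training size is `floor(N * fraction)`).
#'
#' @param n Number of samples.
#' @param fraction Training fraction in (0, 1) (default 0.5).
#' @param seed Integer seed making the split reproducible.
#' @return List with integer index vectors `train` and `validation`
#'   (disjoint, covering `1:n`).
#' @export
holdout_split <- function(n, fraction = 0.5, seed = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop_nircal("invalid fraction: %s is outside (0, 1)", format(fraction),
                class = "nircal_invalid_fraction")
  }
  n_train <- floor(n * fraction)
  if (n_train < 2L || n - n_train < 2L) {
    stop_nircal("both partitions need >= 2 samples (n = %d, fraction = %s)",
                n, format(fraction), class = "nircal_invalid_fraction")
  }
  train <- with_seed(seed, sort(sample.int(n, n_train)))
  list(train = train, validation = setdiff(seq_len(n), train))
}

#' Holdout validation of a linear calibration
#'
#' Fits the coefficients on the training partition and predicts the
#' validation partition. Following the reporting convention of
#' calibration tables where RMSEC is shared across validation modes,
#' RMSEC and calibration R-squared are computed from the full-data fit.
#'
#' @param design `N x m` predictor matrix (selected channels).
#' @param response Concentrations, length `N`.
#' @param fraction Training fraction (default 0.5).
#' @param seed Split seed.
#' @return A `validation_report`; the split is attached as `$split`.
#' @export
holdout <- function(design, response, fraction = 0.5, seed = 1L) {
  design <- as.matrix(design)
  sp <- holdout_split(length(response), fraction, seed)
  full <- fit_ols(design, response)
  fit_tr <- fit_ols(design[sp$train, , drop = FALSE], response[sp$train])
  pred <- drop(cbind(1, design[sp$validation, , drop = FALSE]) %*%
                 fit_tr$coefficients)
  obs <- response[sp$validation]
  validation_report(rmsec = rmse(response, full$fitted),
                    r2c = r2(response, full$fitted),
                    rmsev = rmse(obs, pred),
                    r2v = r2(obs, pred),
                    observed = obs, predicted = pred,
                    mode = "holdout",
                    extra = list(split = sp, fraction = fraction,
                                 seed = seed))
}
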