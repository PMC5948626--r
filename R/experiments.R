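## Orchestration: the full calibration pipeline (absorbance -> CV band
## filter -> pretreatment -> ANOVA selection -> SMLR -> validation) and the
## acquisition-parameter studies (Savitzky-Golay window sweep, lamp-power
## groups, number of averaged acquisitions).

#' Average replicate acquisitions
#'
#' Collapses the acquisition axis to a single spectrum per sample by
#' averaging `n` acquisitions — the first `n` in stored order by default,
#' or a seeded random subset.
#'
#' @param dataset A `spectra_dataset`.
#' @param n Number of acquisitions to average (default: all).
#' @param randomize Draw the `n` acquisitions at random (without
#'   replacement) instead of taking the first `n`?
#' @param seed Seed for the random subset.
#' @return A `spectra_dataset` with a single (averaged) acquisition.
#' @export
average_acquisitions <- function(dataset, n = NULL, randomize = FALSE,
                                 seed = 1L) {
  tr <- dataset$transflectance
  navail <- dim(tr)[2]
  if (is.null(n)) n <- navail
  if (!is_count(n) || n > navail) {
    stop_nircal("insufficient acquisitions: requested %s of %d",
                format(n), navail, class = "nircal_insufficient_acquisitions")
  }
  keep <- if (randomize) with_seed(seed, sort(sample.int(navail, n)))
          else seq_len(n)
  avg <- apply(tr[, keep, , drop = FALSE], c(1, 3), mean)
  out <- dataset
  out$transflectance <- array(avg, c(dim(tr)[1], 1L, dim(tr)[3]))
  out$metadata$n_averaged <- n
  out
}

## Extract the samples x channels matrix of a single-acquisition dataset.
#' @noRd
spectra_matrix <- function(dataset) {
  tr <- dataset$transflectance
  matrix(tr[, 1L, ], dim(tr)[1], dim(tr)[3])
}

#' Pipeline configuration
#'
#' Options for [run_pipeline()]. `preprocessing` selects the pretreatment
#' applied after absorbance conversion and CV band filtering; the
#' Savitzky-Golay parameters follow the study default (first derivative,
#' second-degree polynomial, 11-point window).
#'
#' @param preprocessing One of `"none"`, `"snv"`, `"msc"`, `"sg"`.
#' @param sg_window,sg_degree,sg_derivative Savitzky-Golay parameters.
#' @param cv_aggregate CV aggregation across samples ([cv_per_wavelength()]).
#' @param alpha,cap ANOVA selection parameters ([select_wavelengths()]).
#' @param split_rule,split_threshold Class split ([split_classes()]).
#' @param p_enter,p_remove Stepwise thresholds ([smlr_fit()]).
#' @param validation `"loocv"` or `"holdout"`.
#' @param fraction,holdout_seed Holdout parameters.
#' @param n_average Acquisitions averaged per sample (default: all).
#' @param selection_in_fold Redo ANOVA selection and stepwise channel
#'   choice inside every LOOCV fold (nested validation) instead of fixing
#'   the channels once on the full data? The default (`FALSE`) mirrors the
#'   usual chemometric reporting but leaks selection information into the
#'   validation estimate; see the package vignette.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(preprocessing = c("sg", "none", "snv", "msc"),
                            sg_window = 11, sg_degree = 2,
                            sg_derivative = 1,
                            cv_aggregate = "mean",
                            alpha = 0.05, cap = 100,
                            split_rule = "median", split_threshold = NULL,
                            p_enter = 0.05, p_remove = 0.10,
                            validation = c("loocv", "holdout"),
                            fraction = 0.5, holdout_seed = 1L,
                            n_average = NULL,
                            selection_in_fold = FALSE) {
  structure(list(preprocessing = match.arg(preprocessing),
                 sg_window = sg_window, sg_degree = sg_degree,
                 sg_derivative = sg_derivative,
                 cv_aggregate = cv_aggregate,
                 alpha = alpha, cap = cap,
                 split_rule = split_rule,
                 split_threshold = split_threshold,
                 p_enter = p_enter, p_remove = p_remove,
                 validation = match.arg(validation),
                 fraction = fraction, holdout_seed = holdout_seed,
                 n_average = n_average,
                 selection_in_fold = isTRUE(selection_in_fold)),
            class = "pipeline_config")
}

## Rethrow any error with the pipeline stage name prepended.
#' @noRd
stage <- function(name, expr) {
  withCallingHandlers(expr, error = function(e) {
    stop(errorCondition(sprintf("[stage %s] %s", name, conditionMessage(e)),
                        class = class(e)))
  })
}

## Pretreatment dispatcher shared by run_pipeline and its nested variant.
#' @noRd
apply_preprocessing <- function(absmat, config) {
  switch(config$preprocessing,
         none = absmat,
         snv = snv(absmat),
         msc = msc(absmat),
         sg = savitzky_golay(absmat, config$sg_window, config$sg_degree,
                             config$sg_derivative))
}

#' Run the full calibration pipeline
#'
#' Absorbance conversion, coefficient-of-variation band removal (the CV is
#' always estimated from the full replicate set, as an instrument-level
#' characterization), pretreatment, ANOVA wavelength selection, stepwise
#' multilinear regression and validation, returning a
#' `validation_report`. The result is fully determined by
#' `(dataset, config)`.
#'
#' @param dataset A `spectra_dataset` with replicate acquisitions.
#' @param config A [pipeline_config()].
#' @return A `validation_report` with the fitted `smlr_model` attached as
#'   `$model` and the selection as `$selection`.
#' @export
run_pipeline <- function(dataset, config = pipeline_config()) {
  avg <- stage("average", average_acquisitions(dataset, config$n_average))
  cvv <- stage("cv", cv_per_wavelength(dataset, config$cv_aggregate))
  bf <- stage("band_filter", remove_noisy_bands(cvv))
  absmat <- stage("absorbance",
                  apply_band_filter(to_absorbance(avg), bf))
  prep <- stage("preprocess", apply_preprocessing(absmat, config))
  y <- dataset$concentrations
  labels <- stage("split",
                  split_classes(y, config$split_rule,
                                t = config$split_threshold))
  sel <- stage("anova",
               select_wavelengths(prep, labels, config$alpha, config$cap))
  xsel <- absorbance_matrix(prep$values[, sel$selected_indices, drop = FALSE],
                            prep$wavelengths[sel$selected_indices],
                            provenance = c(prep$provenance, "anova"))
  model <- stage("smlr",
                 smlr_fit(xsel, y, config$p_enter, config$p_remove))
  ## map term channels (relative to the ANOVA-selected set) back to the
  ## preprocessed grid
  model$terms$channel_global <- sel$selected_indices[model$terms$channel]
  design <- prep$values[, model$terms$channel_global, drop = FALSE]

  rep <- stage("validation", {
    if (config$validation == "loocv") {
      if (config$selection_in_fold) {
        loocv_nested(prep, y, config)
      } else {
        loocv(design, y)
      }
    } else {
      holdout(design, y, config$fraction, config$holdout_seed)
    }
  })
  rep$preprocessing <- pretreatment_label(config)
  rep$n_components_after_filter <- length(sel$selected_indices)
  rep$n_components_after_regression <- nrow(model$terms)
  rep$model <- model
  rep$selection <- sel
  rep$band_filter <- bf
  rep$config_hash <- fnv1a32(unclass(config))
  rep
}

#' @noRd
pretreatment_label <- function(config) {
  switch(config$preprocessing,
         none = "ABS", snv = "ABS+SNV", msc = "ABS+MSC", sg = "ABS+SG")
}

## Nested LOOCV: ANOVA selection and stepwise channel choice are redone on
## every training fold; only the held-out sample is predicted.
#' @noRd
loocv_nested <- function(prep, y, config) {
  n <- length(y)
  pred <- vapply(seq_len(n), function(i) {
    tr <- absorbance_matrix(prep$values[-i, , drop = FALSE],
                            prep$wavelengths, prep$provenance)
    labels <- split_classes(y[-i], config$split_rule,
                            t = config$split_threshold)
    sel <- select_wavelengths(tr, labels, config$alpha, config$cap)
    xsel <- absorbance_matrix(tr$values[, sel$selected_indices, drop = FALSE],
                              tr$wavelengths[sel$selected_indices])
    model <- smlr_fit(xsel, y[-i], config$p_enter, config$p_remove)
    predict(model, absorbance_matrix(prep$values[i, , drop = FALSE],
                                     prep$wavelengths))
  }, numeric(1))
  ## calibration metrics from the full-data selection + fit
  labels <- split_classes(y, config$split_rule, t = config$split_threshold)
  sel <- select_wavelengths(prep, labels, config$alpha, config$cap)
  xsel <- absorbance_matrix(prep$values[, sel$selected_indices, drop = FALSE],
                            prep$wavelengths[sel$selected_indices])
  model <- smlr_fit(xsel, y, config$p_enter, config$p_remove)
  fitted_full <- predict(model, prep)
  validation_report(rmsec = rmse(y, fitted_full), r2c = r2(y, fitted_full),
                    rmsev = rmse(y, pred), r2v = r2(y, pred),
                    observed = y, predicted = pred, mode = "loocv-nested",
                    extra = list(n_folds = n))
}

#' Savitzky-Golay window sweep
#'
#' Reruns the pipeline with `preprocessing = "sg"` for every window size
#' and reports RMSEC/RMSEV per window, plus the best window (minimum
#' RMSEV; ties broken toward the smallest window).
#'
#' @param dataset A `spectra_dataset`.
#' @param windows Odd window sizes (default `seq(5, 21, 2)`).
#' @param config Base [pipeline_config()].
#' @return Data frame with columns `window`, `rmsec`, `rmsev`; the best
#'   window is attached as attribute `"argmin"` and the configuration
#'   fingerprint as `"config_hash"`.
#' @export
sweep_sg_window <- function(dataset, windows = seq(5, 21, 2),
                            config = pipeline_config()) {
  stopifnot(length(windows) >= 1)
  rows <- lapply(windows, function(w) {
    cfg <- config
    cfg$preprocessing <- "sg"
    cfg$sg_window <- w
    rep <- run_pipeline(dataset, cfg)
    data.frame(window = w, rmsec = rep$rmsec, rmsev = rep$rmsev)
  })
  out <- do.call(rbind, rows)
  best <- out$window[order(out$rmsev, out$window)][1]
  attr(out, "argmin") <- best
  attr(out, "config_hash") <- fnv1a32(list(unclass(config), windows))
  out
}

#' Lamp-power group sweep
#'
#' Runs the pipeline on one dataset per received-power target (the S1-S3
#' style groups) and tabulates RMSEC/RMSEV per target.
#'
#' @param datasets Named list of `spectra_dataset`s; names (or each
#'   dataset's `metadata$power_target`) give the power target in ut.
#' @param config A [pipeline_config()].
#' @return Data frame with columns `power_target`, `rmsec`, `rmsev` and a
#'   `"config_hash"` attribute.
#' @export
sweep_power <- function(datasets, config = pipeline_config()) {
  stopifnot(length(datasets) >= 1)
  rows <- lapply(seq_along(datasets), function(i) {
    ds <- datasets[[i]]
    tgt <- if (!is.null(names(datasets)) && nzchar(names(datasets)[i])) {
      as.numeric(names(datasets)[i])
    } else {
      ds$metadata$power_target
    }
    rep <- run_pipeline(ds, config)
    data.frame(power_target = tgt, rmsec = rep$rmsec, rmsev = rep$rmsev)
  })
  out <- do.call(rbind, rows)
  attr(out, "config_hash") <- fnv1a32(unclass(config))
  out
}

#' Acquisition-count sweep
#'
#' Reruns the full pipeline with the spectra averaged over `n = 1, 2, ...`
#' acquisitions, to study how replicate averaging reduces the validation
#' error.
#'
#' @param dataset A `spectra_dataset`.
#' @param counts Acquisition counts (default `1:n_acquisitions`).
#' @param config A [pipeline_config()].
#' @return Data frame with columns `n`, `rmsec`, `rmsev` and a
#'   `"config_hash"` attribute.
#' @export
sweep_acquisitions <- function(dataset, counts = NULL,
                               config = pipeline_config()) {
  navail <- dim(dataset$transflectance)[2]
  if (is.null(counts)) counts <- seq_len(navail)
  if (any(counts > navail)) {
    stop_nircal("insufficient acquisitions: counts exceed %d", navail,
                class = "nircal_insufficient_acquisitions")
  }
  rows <- lapply(counts, function(nn) {
    cfg <- config
    cfg$n_average <- nn
    rep <- run_pipeline(dataset, cfg)
    data.frame(n = nn, rmsec = rep$rmsec, rmsev = rep$rmsev)
  })
  out <- do.call(rbind, rows)
  attr(out, "config_hash") <- fnv1a32(list(unclass(config), counts))
  out
}
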