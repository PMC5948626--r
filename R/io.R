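## Plain-text persistence: datasets as CSV (spectra + concentrations) with
## JSON sidecars for ground truth and configuration; validation reports as
## JSON plus a calibration-table CSV.

## Full-precision numeric formatting so CSV round-trips are bitwise exact.
#' @noRd
num17 <- function(x) sprintf("%.17g", x)

#' Save a spectra dataset to a directory
#'
#' Writes `spectra.csv` (columns: `sample`, `acquisition`, then one column
#' per wavelength with the wavelength in nm as header), `concentrations.csv`
#' (`sample`, `concentration_mg_kg`) and, when given, `groundtruth.json`
#' and `config.json`. Numbers are written at full precision so
#' [load_dataset()] restores them bitwise.
#'
#' @param dataset A `spectra_dataset`.
#' @param dir Output directory (created if missing).
#' @param truth Optional `ground_truth` to serialize.
#' @param config Optional `generator_config` to serialize (its
#'   `background_shape` function is stored deparsed).
#' @return `dir`, invisibly.
#' @export
save_dataset <- function(dataset, dir, truth = NULL, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- dataset$transflectance
  d <- dim(tr)
  header <- c("sample", "acquisition", num17(dataset$wavelengths))
  rows <- character(d[1] * d[2])
  r <- 0L
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      r <- r + 1L
      rows[r] <- paste(c(i, j, num17(tr[i, j, ])), collapse = ",")
    }
  }
  writeLines(c(paste(header, collapse = ","), rows),
             file.path(dir, "spectra.csv"))
  writeLines(c("sample,concentration_mg_kg",
               paste(seq_len(d[1]), num17(dataset$concentrations),
                     sep = ",")),
             file.path(dir, "concentrations.csv"))
  meta <- dataset$metadata
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(truth)) {
    jsonlite::write_json(unclass(truth), file.path(dir, "groundtruth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(config)) {
    cfg <- unclass(config)
    cfg$background_shape <- paste(deparse(cfg$background_shape),
                                  collapse = " ")
    jsonlite::write_json(cfg, file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Load a spectra dataset from a directory
#'
#' Inverse of [save_dataset()]. Malformed files (missing columns,
#' non-numeric cells, wavelength-header mismatches between rows) raise
#' format errors with row/column context rather than crashing downstream.
#'
#' @param dir Directory containing `spectra.csv` and `concentrations.csv`.
#' @return A `spectra_dataset`.
#' @export
load_dataset <- function(dir) {
  spath <- file.path(dir, "spectra.csv")
  cpath <- file.path(dir, "concentrations.csv")
  for (p in c(spath, cpath)) {
    if (!file.exists(p)) {
      stop_nircal("format error: missing file %s", p, class = "nircal_format")
    }
  }
  sp <- utils::read.csv(spath, check.names = FALSE)
  if (ncol(sp) < 3L || !all(c("sample", "acquisition") %in% names(sp)[1:2])) {
    stop_nircal("format error: spectra.csv must start with sample, acquisition",
                class = "nircal_format")
  }
  wl <- suppressWarnings(as.numeric(names(sp)[-(1:2)]))
  if (anyNA(wl)) {
    stop_nircal("format error: non-numeric wavelength header in column(s) %s",
                paste(which(is.na(wl)) + 2L, collapse = ", "),
                class = "nircal_format")
  }
  vals <- as.matrix(sp[, -(1:2), drop = FALSE])
  if (!is.numeric(vals) || anyNA(vals)) {
    bad <- which(is.na(suppressWarnings(apply(vals, 1, as.numeric))))[1]
    stop_nircal("format error: non-numeric spectral value near row %s",
                format(bad), class = "nircal_format")
  }
  samples <- sort(unique(sp$sample))
  acqs <- sort(unique(sp$acquisition))
  tr <- array(NA_real_, c(length(samples), length(acqs), length(wl)))
  for (r in seq_len(nrow(sp))) {
    tr[match(sp$sample[r], samples), match(sp$acquisition[r], acqs), ] <-
      vals[r, ]
  }
  if (anyNA(tr)) {
    stop_nircal("format error: incomplete sample x acquisition grid",
                class = "nircal_format")
  }
  cc <- utils::read.csv(cpath)
  if (!all(c("sample", "concentration_mg_kg") %in% names(cc))) {
    stop_nircal("format error: concentrations.csv needs sample, concentration_mg_kg",
                class = "nircal_format")
  }
  if (nrow(cc) != length(samples)) {
    stop_nircal("format error: %d concentrations for %d samples", nrow(cc),
                length(samples), class = "nircal_format")
  }
  conc <- cc$concentration_mg_kg[match(samples, cc$sample)]
  meta <- list()
  mpath <- file.path(dir, "metadata.json")
  if (file.exists(mpath)) meta <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  structure(list(transflectance = tr, wavelengths = wl,
                 concentrations = as.numeric(conc), metadata = meta),
            class = "spectra_dataset")
}

#' Tabulate validation reports as a calibration table
#'
#' One row per report, with the conventional calibration-table columns
#' (preprocessing label, validation mode, component counts, RMSEC/RMSEV in
#' mg/kg and the calibration/validation determination coefficients).
#'
#' @param reports A `validation_report` or list of them.
#' @return Data frame.
#' @export
report_table <- function(reports) {
  if (inherits(reports, "validation_report")) reports <- list(reports)
  do.call(rbind, lapply(reports, function(r) {
    df <- data.frame("SMLR", r$preprocessing, toupper(r$mode),
                     r$n_components_after_filter,
                     r$n_components_after_regression,
                     r$rmsec, r$r2c, r$rmsev, r$r2v,
                     check.names = FALSE)
    names(df) <- c("Regression Algorithm", "Preprocessing Algorithm",
                   "Validation", "Number of Components after Filtering",
                   "Number of Components after Regression", "RMSEC (mg/kg)",
                   "Rc2", "RMSEV (mg/kg)", "Rv2")
    df
  }))
}

#' Save a validation report
#'
#' Writes `<path>.json` (metrics, per-sample observed/predicted pairs,
#' model terms if present, configuration fingerprint) and `<path>.csv`
#' (the [report_table()] row).
#'
#' @param report A `validation_report`.
#' @param path Output path prefix (without extension).
#' @return `path`, invisibly.
#' @export
save_report <- function(report, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  payload <- list(rmsec = report$rmsec, r2c = report$r2c,
                  rmsev = report$rmsev, r2v = report$r2v,
                  n_components_after_filter =
                    report$n_components_after_filter,
                  n_components_after_regression =
                    report$n_components_after_regression,
                  preprocessing = report$preprocessing,
                  mode = report$mode,
                  pairs = report$pairs,
                  config_hash = report$config_hash)
  if (!is.null(report$model)) {
    payload$model <- list(intercept = report$model$intercept,
                          terms = report$model$terms)
  }
  jsonlite::write_json(payload, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  utils::write.csv(report_table(report), paste0(path, ".csv"),
                   row.names = FALSE)
  invisible(path)
}
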