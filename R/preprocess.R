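## Spectral pretreatment operators. All operate on an `absorbance_matrix`
## (samples x channels, with its wavelength grid and a provenance chain)
## except the coefficient-of-variation screen, which works on the raw
## replicate transflectance where the mean signal is far from zero.

#' Construct an absorbance matrix container
#'
#' @param values Numeric `samples x channels` matrix.
#' @param wavelengths Wavelength grid in nm, one per column.
#' @param provenance Character vector naming the operators already applied.
#' @return An `absorbance_matrix` object.
#' @export
absorbance_matrix <- function(values, wavelengths,
                              provenance = character()) {
  values <- as.matrix(values)
  if (ncol(values) != length(wavelengths)) {
    stop_nircal("shape error: %d columns but %d wavelengths",
                ncol(values), length(wavelengths), class = "nircal_shape")
  }
  structure(list(values = values, wavelengths = as.numeric(wavelengths),
                 provenance = provenance),
            class = "absorbance_matrix")
}

#' @export
print.absorbance_matrix <- function(x, ...) {
  cat(sprintf("<absorbance_matrix> %d x %d (%.0f-%.0f nm); chain: %s\n",
              nrow(x$values), ncol(x$values), min(x$wavelengths),
              max(x$wavelengths),
              if (length(x$provenance)) paste(x$provenance, collapse = " -> ")
              else "<raw>"))
  invisible(x)
}

#' Transflectance to absorbance conversion
#'
#' Elementwise `log10(1/x)`. Accepts a plain `samples x channels` matrix
#' (with `wavelengths` supplied) or a single-acquisition `spectra_dataset`
#' (e.g. the output of [average_acquisitions()]). Raw detector units above
#' 1 ut give negative absorbance; downstream operators are offset-invariant
#' so only relative absorbance matters.
#'
#' @param x Matrix or `spectra_dataset` of strictly positive values.
#' @param wavelengths Wavelength grid, required when `x` is a bare matrix.
#' @return An `absorbance_matrix`.
#' @export
to_absorbance <- function(x, wavelengths = NULL) {
  if (inherits(x, "spectra_dataset")) {
    tr <- x$transflectance
    if (dim(tr)[2] != 1L) {
      stop_nircal(paste0("to_absorbance expects one spectrum per sample; ",
                         "average acquisitions first"),
                  class = "nircal_shape")
    }
    m <- tr[, 1L, , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = dim(tr)[1])
    wavelengths <- x$wavelengths
  } else {
    m <- as.matrix(x)
    if (is.null(wavelengths)) wavelengths <- seq_len(ncol(m))
  }
  bad <- which(m <= 0, arr.ind = TRUE)
  if (nrow(bad <- as.matrix(bad)) > 0) {
    stop_nircal("nonpositive signal at (sample, channel): %s",
                paste(utils::head(apply(bad, 1, paste, collapse = ","), 5),
                      collapse = "; "),
                class = "nircal_nonpositive_signal")
  }
  absorbance_matrix(log10(1 / m), wavelengths, provenance = "absorbance")
}

#' Per-wavelength coefficient of variation
#'
#' For every sample and channel, `CV = 100 * s / mean` across the replicate
#' acquisitions (unbiased SD); the per-channel value returned is either the
#' unweighted mean over samples (`aggregate = "mean"`, the default) or the
#' pooled CV computed from pooled within-sample variance and the grand mean
#' (`aggregate = "pooled"`).
#'
#' @param dataset A `spectra_dataset` with >= 2 acquisitions per sample.
#' @param aggregate Aggregation of per-sample CVs across samples.
#' @return Numeric vector of per-channel CV values, in percent.
#' @export
cv_per_wavelength <- function(dataset, aggregate = c("mean", "pooled")) {
  aggregate <- match.arg(aggregate)
  st <- replicate_statistics(dataset)
  if (any(st$mean == 0)) {
    bad <- which(st$mean == 0, arr.ind = TRUE)[1, ]
    stop_nircal("division degenerate: zero replicate mean at sample %d, channel %d",
                bad[1], bad[2], class = "nircal_division_degenerate")
  }
  if (aggregate == "mean") {
    colMeans(100 * st$sd / st$mean)
  } else {
    100 * sqrt(colMeans(st$sd^2)) / colMeans(st$mean)
  }
}

#' Coefficient-of-variation band filter
#'
#' Flags noisy spectral bands: the threshold is the mean CV over all
#' channels and every channel whose CV strictly exceeds it is removed
#' (ties are kept).
#'
#' @param cv Per-channel CV vector in percent (finite).
#' @return A `band_filter_result` with `cv`, `threshold` and the logical
#'   `retained_mask`.
#' @export
remove_noisy_bands <- function(cv) {
  if (!all(is.finite(cv))) {
    stop_nircal("CV values must be finite", class = "nircal_invalid_design")
  }
  threshold <- mean(cv)
  mask <- cv <= threshold
  if (!any(mask)) {
    stop_nircal("empty spectrum: the CV filter removed every channel",
                class = "nircal_empty_spectrum")
  }
  structure(list(cv = cv, threshold = threshold, retained_mask = mask),
            class = "band_filter_result")
}

#' Restrict an absorbance matrix to the retained channels
#'
#' @param spectra An `absorbance_matrix`.
#' @param filter A `band_filter_result` (or a logical/integer channel
#'   selector of matching length).
#' @return The filtered `absorbance_matrix`.
#' @export
apply_band_filter <- function(spectra, filter) {
  mask <- if (inherits(filter, "band_filter_result")) filter$retained_mask
          else filter
  if (is.logical(mask) && length(mask) != ncol(spectra$values)) {
    stop_nircal("shape error: filter length %d vs %d channels",
                length(mask), ncol(spectra$values), class = "nircal_shape")
  }
  absorbance_matrix(spectra$values[, mask, drop = FALSE],
                    spectra$wavelengths[mask],
                    provenance = c(spectra$provenance, "band_filter"))
}

#' Standard normal variate
#'
#' Row-wise standardization: each spectrum has its mean subtracted and is
#' divided by its standard deviation (`n - 1` denominator), removing
#' additive offsets and multiplicative scatter.
#'
#' @param spectra An `absorbance_matrix` whose rows have >= 2 channels and
#'   nonzero variance.
#' @return The transformed `absorbance_matrix`.
#' @export
snv <- function(spectra) {
  v <- spectra$values
  if (ncol(v) < 2L) {
    stop_nircal("SNV needs at least 2 channels per spectrum",
                class = "nircal_degenerate_spectrum")
  }
  mu <- rowMeans(v)
  s <- apply(v, 1, stats::sd)
  zero <- which(s == 0)
  if (length(zero)) {
    stop_nircal("degenerate spectrum: zero variance in row(s) %s",
                paste(zero, collapse = ", "),
                class = "nircal_degenerate_spectrum")
  }
  absorbance_matrix((v - mu) / s, spectra$wavelengths,
                    provenance = c(spectra$provenance, "snv"))
}

#' Multiplicative scatter correction
#'
#' Each spectrum is regressed on the reference spectrum (by default the
#' column-wise mean spectrum of the input) by ordinary least squares,
#' `x_i = a_i + b_i * ref + e_i`, and corrected as `(x_i - a_i) / b_i`.
#'
#' @param spectra An `absorbance_matrix`; at least 2 rows when `reference`
#'   is omitted.
#' @param reference Optional reference spectrum (length = channels).
#' @return The corrected `absorbance_matrix`; the fitted `(a, b)` pairs are
#'   attached as attribute `"msc_coefficients"`.
#' @export
msc <- function(spectra, reference = NULL) {
  v <- spectra$values
  if (is.null(reference)) {
    if (nrow(v) < 2L) {
      stop_nircal("MSC needs >= 2 spectra when no reference is given",
                  class = "nircal_degenerate_spectrum")
    }
    reference <- colMeans(v)
  }
  if (length(reference) != ncol(v)) {
    stop_nircal("shape error: reference length %d vs %d channels",
                length(reference), ncol(v), class = "nircal_shape")
  }
  rc <- reference - mean(reference)
  den <- sum(rc^2)
  if (den == 0) {
    stop_nircal("uncorrectable spectrum: constant reference",
                class = "nircal_uncorrectable_spectrum")
  }
  b <- as.vector(v %*% rc) / den
  a <- rowMeans(v) - b * mean(reference)
  if (any(abs(b) < 1e-12)) {
    stop_nircal("uncorrectable spectrum: near-zero slope in row(s) %s",
                paste(which(abs(b) < 1e-12), collapse = ", "),
                class = "nircal_uncorrectable_spectrum")
  }
  out <- absorbance_matrix((v - a) / b, spectra$wavelengths,
                           provenance = c(spectra$provenance, "msc"))
  attr(out, "msc_coefficients") <- cbind(a = a, b = b)
  out
}

#' Savitzky-Golay convolution coefficients
#'
#' Least-squares polynomial filter coefficients for a centred window:
#' fitting a degree-`degree` polynomial to the `window` points and reading
#' off the `derivative`-th derivative at the centre. Derivatives are with
#' respect to the channel index (multiply by `derivative`-th power of the
#' reciprocal channel spacing for per-nm units).
#'
#' @param window Odd window size (> degree).
#' @param degree Polynomial degree.
#' @param derivative Derivative order (0 = smoothing), `<= degree`.
#' @return Numeric vector of `window` convolution coefficients.
#' @examples
#' sg_coefficients(5, 2, 0) * 35  # the classic (-3, 12, 17, 12, -3)
#' @export
sg_coefficients <- function(window, degree, derivative = 0) {
  if (!is_count(window) || window %% 2 == 0) {
    stop_nircal("invalid parameters: window must be a positive odd integer",
                class = "nircal_invalid_parameters")
  }
  if (degree >= window || derivative > degree || derivative < 0) {
    stop_nircal("invalid parameters: need window > degree >= derivative >= 0",
                class = "nircal_invalid_parameters")
  }
  h <- (window - 1L) / 2L
  z <- seq(-h, h)
  A <- outer(z, 0:degree, `^`)
  ## row (derivative+1) of the pseudoinverse, scaled by derivative!
  pinv <- solve(crossprod(A), t(A))
  factorial(derivative) * pinv[derivative + 1L, ]
}

#' Savitzky-Golay filtering of spectra
#'
#' Convolution with [sg_coefficients()]. Only channels with a full window
#' are kept: `(window - 1) / 2` channels are dropped at each edge and the
#' wavelength grid is shortened accordingly.
#'
#' @param spectra An `absorbance_matrix` with at least `window` channels.
#' @param window Odd window size.
#' @param degree Polynomial degree (`< window`).
#' @param derivative Derivative order (`<= degree`); derivatives are per
#'   channel step.
#' @return The filtered `absorbance_matrix`.
#' @export
savitzky_golay <- function(spectra, window = 11, degree = 2,
                           derivative = 1) {
  coef <- sg_coefficients(window, degree, derivative)
  v <- spectra$values
  nwl <- ncol(v)
  if (nwl < window) {
    stop_nircal("invalid parameters: window %d exceeds %d channels",
                window, nwl, class = "nircal_invalid_parameters")
  }
  h <- (window - 1L) / 2L
  nout <- nwl - 2L * h
  out <- matrix(0, nrow(v), nout)
  for (k in seq_len(window)) {
    out <- out + coef[k] * v[, k:(k + nout - 1L), drop = FALSE]
  }
  absorbance_matrix(out, spectra$wavelengths[(h + 1L):(nwl - h)],
                    provenance = c(spectra$provenance,
                                   sprintf("sg(%d,%d,%d)", window, degree,
                                           derivative)))
}
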