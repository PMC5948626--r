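## ANOVA-based wavelength screening: samples are split into high/low
## polyphenol classes and each channel is tested with a one-way ANOVA
## F-statistic; significant channels are ranked by F and capped.

#' Split samples into low/high concentration classes
#'
#' @param concentrations Sample concentrations in mg/kg.
#' @param rule `"median"` (values `<=` the median go to the low class) or
#'   `"threshold"` with an explicit boundary `t` (values `<= t` are low).
#' @param t Threshold in mg/kg when `rule = "threshold"`.
#' @return Factor with levels `low`, `high`.
#' @export
split_classes <- function(concentrations, rule = c("median", "threshold"),
                          t = NULL) {
  rule <- match.arg(rule)
  if (length(concentrations) < 2L) {
    stop_nircal("degenerate split: need at least 2 samples",
                class = "nircal_degenerate_split")
  }
  bound <- if (rule == "median") stats::median(concentrations) else {
    if (is.null(t)) {
      stop_nircal("degenerate split: rule 'threshold' needs t",
                  class = "nircal_degenerate_split")
    }
    t
  }
  lab <- factor(ifelse(concentrations <= bound, "low", "high"),
                levels = c("low", "high"))
  if (any(table(lab) == 0)) {
    stop_nircal("degenerate split: a class is empty at boundary %s mg/kg",
                format(bound), class = "nircal_degenerate_split")
  }
  lab
}

## Vectorized one-way ANOVA over the columns of a matrix, two classes.
## Returns F, p and the (k-1, N-k) degrees of freedom.
#' @noRd
anova_f_matrix <- function(values, labels) {
  labels <- as.factor(labels)
  k <- nlevels(droplevels(labels))
  n <- nrow(values)
  if (k < 2L) {
    stop_nircal("degenerate split: need 2 classes", class = "nircal_degenerate_split")
  }
  if (n < 3L) {
    stop_nircal("need at least 3 samples for ANOVA", class = "nircal_invalid_design")
  }
  idx <- split(seq_len(n), droplevels(labels))
  grand <- colMeans(values)
  ssb <- 0
  ssw <- 0
  for (ii in idx) {
    gm <- colMeans(values[ii, , drop = FALSE])
    ssb <- ssb + length(ii) * (gm - grand)^2
    ssw <- ssw + colSums((values[ii, , drop = FALSE] -
                            matrix(gm, length(ii), ncol(values),
                                   byrow = TRUE))^2)
  }
  df1 <- k - 1L
  df2 <- n - k
  f <- (ssb / df1) / (ssw / df2)
  ## ties/degeneracies: equal group means -> F = 0, p = 1; zero within-group
  ## variance with distinct means -> F = Inf, p = 0
  eps <- .Machine$double.eps
  zero_between <- ssb <= eps * pmax(ssw, 1)
  f[zero_between] <- 0
  f[!zero_between & ssw == 0] <- Inf
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  p[f == 0] <- 1
  p[is.infinite(f)] <- 0
  list(f = f, p = p, df = c(df1, df2))
}

#' One-way ANOVA F-test for a single feature
#'
#' `F = (between-group SS / (k - 1)) / (within-group SS / (N - k))`, with
#' the p-value from the upper tail of the F distribution on
#' `(k - 1, N - k)` degrees of freedom. Zero within-group variance with
#' distinct group means reports `F = Inf`, `p = 0`.
#'
#' @param values Numeric response vector.
#' @param labels Two-level class labels, one per value.
#' @return List with `f`, `p` and `df = c(k - 1, N - k)`.
#' @examples
#' anova_f(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
anova_f <- function(values, labels) {
  res <- anova_f_matrix(matrix(values, ncol = 1L), labels)
  list(f = unname(res$f), p = unname(res$p), df = res$df)
}

#' ANOVA wavelength selection
#'
#' Tests every channel with [anova_f()] against the class labels, keeps
#' channels with `p < alpha`, ranks them by descending F (ties broken by
#' lower channel index) and truncates at `cap`.
#'
#' @param spectra An `absorbance_matrix`.
#' @param labels Two-level class labels, one per sample (row).
#' @param alpha Significance level (default 0.05).
#' @param cap Maximum number of retained channels (default 100).
#' @return A `wavelength_selection`: `f_values`, `p_values`, `df`,
#'   `selected_indices` (ordered), `selected_wavelengths`, `alpha`, `cap`.
#' @export
select_wavelengths <- function(spectra, labels, alpha = 0.05, cap = 100) {
  v <- spectra$values
  if (nrow(v) != length(labels)) {
    stop_nircal("shape error: %d samples vs %d labels", nrow(v),
                length(labels), class = "nircal_shape")
  }
  res <- anova_f_matrix(v, labels)
  sig <- which(res$p < alpha)
  if (!length(sig)) {
    stop_nircal("empty selection: no channel is significant at alpha = %s",
                format(alpha), class = "nircal_empty_selection")
  }
  ord <- sig[order(-res$f[sig], sig)]
  sel <- utils::head(ord, cap)
  structure(list(f_values = res$f, p_values = res$p, df = res$df,
                 labels = labels,
                 selected_indices = sel,
                 selected_wavelengths = spectra$wavelengths[sel],
                 alpha = alpha, cap = cap),
            class = "wavelength_selection")
}

#' @export
print.wavelength_selection <- function(x, ...) {
  cat(sprintf(paste0("<wavelength_selection> %d channels at p < %s",
                     " (cap %d), df = (%d, %d)\n"),
              length(x$selected_indices), format(x$alpha), x$cap,
              x$df[1], x$df[2]))
  cat("  top wavelengths (nm):",
      paste(round(utils::head(x$selected_wavelengths, 5), 1),
            collapse = ", "), "\n")
  invisible(x)
}
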