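## Stepwise multilinear regression: forward entry / backward elimination of
## spectral channels driven by partial F-tests on the residual sum of
## squares, producing a small linear model
## `y-hat = beta0 + sum_k beta_k x_k`.

#' Ordinary least squares with standard errors
#'
#' Fits `response ~ 1 + design` by QR decomposition and returns the pieces
#' the stepwise procedure needs: coefficients, residual sum of squares and
#' per-coefficient standard errors from the unbiased residual variance.
#'
#' @param design Numeric `N x m` matrix of predictors (no intercept
#'   column; `m = 0` allowed).
#' @param response Numeric response vector of length `N > m + 1`.
#' @return List with `coefficients` (intercept first), `se`, `rss`,
#'   `df_residual`, `fitted`, `residuals`.
#' @export
fit_ols <- function(design, response) {
  if (is.null(design)) design <- matrix(numeric(0), length(response), 0)
  design <- as.matrix(design)
  n <- length(response)
  m <- ncol(design)
  if (nrow(design) != n) {
    stop_nircal("shape error: %d rows vs %d responses", nrow(design), n,
                class = "nircal_shape")
  }
  if (n <= m + 1L) {
    stop_nircal("need N > m + 1 (N = %d, m = %d)", n, m,
                class = "nircal_invalid_design")
  }
  x <- cbind(`(Intercept)` = 1, design)
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    dropped <- colnames(x)[qr_x$pivot[(qr_x$rank + 1L):ncol(x)]]
    stop_nircal("collinear design: column(s) %s",
                paste(dropped, collapse = ", "),
                class = "nircal_collinear_design")
  }
  beta <- qr.coef(qr_x, response)
  res <- response - drop(x %*% beta)
  rss <- sum(res^2)
  df <- n - ncol(x)
  sigma2 <- rss / df
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(pmax(diag(xtx_inv) * sigma2, 0))
  names(se) <- names(beta)
  list(coefficients = beta, se = se, rss = rss, df_residual = df,
       fitted = response - res, residuals = res)
}

#' Partial F-test between nested OLS fits
#'
#' Tests whether the larger model (one extra predictor) significantly
#' reduces the residual sum of squares:
#' `F = (RSS_without - RSS_with) / (RSS_with / df_with)`, with the p-value
#' from the F distribution on `(1, df_with)` degrees of freedom. A
#' zero-residual enlarged fit is reported as a perfect-fit signal
#' (`F = Inf`, `p = 0`).
#'
#' @param fit_without,fit_with Results of [fit_ols()] on the same samples,
#'   `fit_with` having exactly one more predictor.
#' @return List with `f` and `p`.
#' @export
partial_test <- function(fit_without, fit_with) {
  if (fit_with$df_residual != fit_without$df_residual - 1L) {
    stop_nircal("partial test expects nested fits differing by one term",
                class = "nircal_invalid_design")
  }
  if (fit_with$rss <= 0 ||
      fit_with$rss < 1e-14 * max(fit_without$rss, 1)) {
    return(list(f = Inf, p = 0))
  }
  f <- max(fit_without$rss - fit_with$rss, 0) /
    (fit_with$rss / fit_with$df_residual)
  list(f = f, p = stats::pf(f, 1, fit_with$df_residual, lower.tail = FALSE))
}

## Candidate matrix coercion: accept an absorbance_matrix or a plain matrix
#' @noRd
as_design <- function(x) {
  if (inherits(x, "absorbance_matrix")) {
    list(values = x$values, wavelengths = x$wavelengths)
  } else {
    m <- as.matrix(x)
    wl <- attr(x, "wavelengths")
    if (is.null(wl)) wl <- as.numeric(seq_len(ncol(m)))
    list(values = m, wavelengths = wl)
  }
}

#' Stepwise multilinear regression
#'
#' Builds a sparse linear calibration model by iterating forward entry and
#' backward elimination:
#' \enumerate{
#'   \item Forward: among channels not in the model, find the one whose
#'     partial F-test against the current model has the smallest p-value
#'     (ties: largest F, then lowest channel index); add it if
#'     `p < p_enter`.
#'   \item Backward: while any included channel's coefficient has
#'     `p > p_remove` (squared-t test in the current fit), remove the
#'     largest-p one.
#'   \item Stop when neither step applies, or when another entry would
#'     leave `N - m - 1 <= 1` residual degrees of freedom.
#' }
#' `p_remove >= p_enter` is required, which rules out add/remove cycles.
#' If no channel ever enters, the intercept-only model is returned with
#' `intercept_only = TRUE` (a warning flag, not an error).
#'
#' @param x Candidate predictors: an `absorbance_matrix` (typically already
#'   restricted to ANOVA-selected channels) or a plain matrix with an
#'   optional `"wavelengths"` attribute.
#' @param response Concentrations in mg/kg.
#' @param p_enter Entry significance threshold (default 0.05).
#' @param p_remove Removal threshold (default 0.10, must exceed `p_enter`).
#' @return An `smlr_model`: `intercept`, `terms` (data frame of channel,
#'   wavelength, coefficient), `trace` (per-step log of action, channel, F,
#'   p, RSS), `p_enter`, `p_remove`, `intercept_only`.
#' @export
smlr_fit <- function(x, response, p_enter = 0.05, p_remove = 0.10) {
  d <- as_design(x)
  v <- d$values
  n <- length(response)
  if (nrow(v) != n) {
    stop_nircal("shape error: %d spectra vs %d responses", nrow(v), n,
                class = "nircal_shape")
  }
  if (n < 3L) {
    stop_nircal("need at least 3 samples", class = "nircal_invalid_design")
  }
  if (p_remove < p_enter) {
    stop_nircal("require p_remove >= p_enter to prevent add/remove cycles",
                class = "nircal_invalid_parameters")
  }

  included <- integer(0)
  trace <- list()
  log_step <- function(action, channel, f, p, rss) {
    trace[[length(trace) + 1L]] <<- data.frame(
      step = length(trace) + 1L, action = action, channel = channel,
      f = f, p = p, rss = rss)
  }
  fit <- fit_ols(NULL, response)

  ss_tot <- sum((response - mean(response))^2)
  repeat {
    acted <- FALSE
    ## forward entry (degrees-of-freedom guard: adding must leave
    ## N - m - 1 > 1; a numerically perfect fit cannot be improved)
    if (fit$rss > 1e-10 * ss_tot &&
        n - (length(included) + 1L) - 1L > 1L) {
      cand <- setdiff(seq_len(ncol(v)), included)
      ## drop candidates collinear with the current design
      best <- NULL
      for (j in cand) {
        fit_j <- tryCatch(
          fit_ols(v[, c(included, j), drop = FALSE], response),
          nircal_collinear_design = function(e) NULL)
        if (is.null(fit_j)) next
        pt <- partial_test(fit, fit_j)
        if (is.null(best) || pt$p < best$p ||
            (pt$p == best$p && pt$f > best$f)) {
          best <- list(j = j, p = pt$p, f = pt$f, fit = fit_j)
        }
      }
      if (!is.null(best) && best$p < p_enter) {
        included <- c(included, best$j)
        fit <- best$fit
        log_step("add", best$j, best$f, best$p, fit$rss)
        acted <- TRUE
      }
    }
    ## backward elimination on coefficient significance
    repeat {
      if (!length(included)) break
      tstat <- fit$coefficients[-1L] / fit$se[-1L]
      pvals <- 2 * stats::pt(abs(tstat), fit$df_residual, lower.tail = FALSE)
      worst <- which.max(pvals)
      if (pvals[worst] > p_remove) {
        ch <- included[worst]
        included <- included[-worst]
        log_step("remove", ch,
                 unname(tstat[worst]^2), unname(pvals[worst]), NA_real_)
        fit <- fit_ols(v[, included, drop = FALSE], response)
        trace[[length(trace)]]$rss <- fit$rss
        acted <- TRUE
      } else break
    }
    if (!acted) break
  }

  terms <- data.frame(channel = included,
                      wavelength = d$wavelengths[included],
                      coefficient = unname(fit$coefficients[-1L]))
  structure(list(intercept = unname(fit$coefficients[1L]),
                 terms = terms,
                 trace = if (length(trace)) do.call(rbind, trace)
                         else data.frame(step = integer(), action = character(),
                                         channel = integer(), f = numeric(),
                                         p = numeric(), rss = numeric()),
                 p_enter = p_enter, p_remove = p_remove,
                 rss = fit$rss,
                 intercept_only = length(included) == 0L),
            class = "smlr_model")
}

#' @export
print.smlr_model <- function(x, ...) {
  cat(sprintf("<smlr_model> intercept %.4g + %d term(s)\n", x$intercept,
              nrow(x$terms)))
  if (nrow(x$terms)) {
    for (i in seq_len(nrow(x$terms))) {
      cat(sprintf("  %8.1f nm  beta = %.6g\n", x$terms$wavelength[i],
                  x$terms$coefficient[i]))
    }
  }
  if (x$intercept_only) cat("  (no channel passed the entry test)\n")
  invisible(x)
}

#' Predict concentrations from an SMLR model
#'
#' `y-hat = beta0 + sum_k beta_k x_k`. Model channels are matched to the
#' spectra by wavelength (nearest channel within half a grid step).
#'
#' @param object An `smlr_model`.
#' @param newdata An `absorbance_matrix` (or plain matrix with a
#'   `"wavelengths"` attribute) containing the model's channels.
#' @param ... Unused.
#' @return Numeric vector of predictions, mg/kg.
#' @export
predict.smlr_model <- function(object, newdata, ...) {
  d <- as_design(newdata)
  if (!nrow(object$terms)) {
    return(rep(object$intercept, nrow(d$values)))
  }
  tol <- if (length(d$wavelengths) > 1L) min(diff(d$wavelengths)) / 2
         else Inf
  idx <- vapply(object$terms$wavelength, function(w) {
    j <- which.min(abs(d$wavelengths - w))
    if (abs(d$wavelengths[j] - w) > tol) NA_integer_ else j
  }, integer(1))
  if (anyNA(idx)) {
    stop_nircal("model mismatch: wavelength(s) %s nm not present in spectra",
                paste(object$terms$wavelength[is.na(idx)], collapse = ", "),
                class = "nircal_model_mismatch")
  }
  drop(object$intercept +
         d$values[, idx, drop = FALSE] %*% object$terms$coefficient)
}
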