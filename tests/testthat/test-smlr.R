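test_that("OLS recovers exact linear relations and matches normal equations", {
  x <- matrix(seq(0.1, 2, length.out = 10))
  y <- 3 + 2 * x[, 1]
  f <- fit_ols(x, y)
  expect_equal(unname(f$coefficients), c(3, 2), tolerance = 1e-10)
  expect_lt(f$rss, 1e-20)

  f0 <- fit_ols(NULL, y)
  expect_equal(unname(f0$coefficients), mean(y))

  set.seed(20)
  d <- small_design()
  f <- fit_ols(d$x, d$y)
  xx <- cbind(1, d$x)
  beta_or <- solve(crossprod(xx), crossprod(xx, d$y))
  expect_equal(unname(f$coefficients), drop(beta_or), tolerance = 1e-8)
  res <- d$y - drop(xx %*% beta_or)
  expect_equal(f$rss, sum(res^2), tolerance = 1e-8)
  se_or <- sqrt(diag(solve(crossprod(xx))) * sum(res^2) /
                  (nrow(xx) - ncol(xx)))
  expect_equal(unname(f$se), unname(se_or), tolerance = 1e-8)

  expect_error(fit_ols(cbind(d$x, d$x[, 1]), d$y),
               class = "nircal_collinear_design")
  expect_error(fit_ols(matrix(rnorm(6), 3, 2), rnorm(3)),
               class = "nircal_invalid_design")
})

test_that("partial F-test matches the squared t of the added coefficient", {
  set.seed(21)
  for (k in 1:20) {
    n <- sample(8:20, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    y <- rnorm(n) + x[, 1]
    small <- fit_ols(x[, 1:2], y)
    big <- fit_ols(x, y)
    pt <- partial_test(small, big)
    tsq <- (big$coefficients[4] / big$se[4])^2
    expect_equal(pt$f, unname(tsq), tolerance = 1e-8)
    pv <- 2 * stats::pt(abs(big$coefficients[4] / big$se[4]),
                        big$df_residual, lower.tail = FALSE)
    expect_equal(pt$p, unname(pv), tolerance = 1e-8)
  }

  # candidate orthogonal to residuals -> F ~ 0; candidate equal to the
  # residual vector -> perfect-fit signal
  n <- 20
  set.seed(22)
  x1 <- rnorm(n)
  y <- 2 * x1 + rnorm(n)
  f1 <- fit_ols(matrix(x1), y)
  f2 <- fit_ols(cbind(x1, f1$residuals), y)
  expect_equal(partial_test(f1, f2)$p, 0)
})

test_that("stepwise selects the true channel in a noiseless single-channel system", {
  set.seed(23)
  x <- matrix(rnorm(15 * 8), 15, 8)
  y <- 5 + 3 * x[, 4]
  m <- smlr_fit(x, y)
  expect_equal(m$terms$channel, 4)
  expect_lt(m$rss, 1e-16)
  expect_false(m$intercept_only)
  expect_equal(m$trace$action, "add")
})

test_that("stepwise stays intercept-only under the null at the multiple-candidate rate", {
  # With m independent null candidates the first forward step enters with
  # probability 1 - (1 - p_enter)^m (the procedure applies no multiplicity
  # correction), so intercept-only models appear at ~ (1 - 0.05)^20 = 36%.
  hits <- vapply(1:50, function(seed) {
    set.seed(seed)
    x <- matrix(rnorm(15 * 20), 15, 20)
    y <- rnorm(15)
    m <- smlr_fit(x, y, p_enter = 0.05, p_remove = 0.10)
    m$intercept_only
  }, logical(1))
  p0 <- 0.95^20
  se <- sqrt(p0 * (1 - p0) / 50)
  expect_lt(abs(mean(hits) - p0), 4 * se)
})

test_that("entry thresholds act as guards", {
  set.seed(24)
  x <- matrix(rnorm(12 * 12), 12, 12)
  y <- 2 * x[, 1] + rnorm(12, sd = 0.01)
  # p_enter = 0: nothing can enter
  m0 <- smlr_fit(x, y, p_enter = 0, p_remove = 0.1)
  expect_true(m0$intercept_only)
  # p_enter = p_remove = 1: greedy addition until the df guard stops it
  m1 <- smlr_fit(x, y, p_enter = 1, p_remove = 1)
  expect_equal(nrow(m1$terms), 12 - 3)  # N - m - 1 > 1 bound
  expect_error(smlr_fit(x, y, p_enter = 0.5, p_remove = 0.1),
               class = "nircal_invalid_parameters")
})

test_that("stepwise entry decisions match exhaustive partial-F recomputation", {
  set.seed(25)
  for (rep in 1:10) {
    n <- 14
    x <- matrix(rnorm(n * 5), n, 5)
    y <- x[, 2] - 0.8 * x[, 5] + rnorm(n, sd = 0.4)
    m <- smlr_fit(x, y, p_enter = 0.05, p_remove = 0.10)
    # replay: at each 'add', recompute every candidate's partial F by brute
    # force and verify the chosen channel attains the minimal p
    included <- integer(0)
    for (step in seq_len(nrow(m$trace))) {
      row <- m$trace[step, ]
      if (row$action != "add") {
        included <- setdiff(included, row$channel)
        next
      }
      base <- fit_ols(x[, included, drop = FALSE], y)
      ps <- sapply(setdiff(1:5, included), function(j) {
        fj <- fit_ols(x[, c(included, j), drop = FALSE], y)
        partial_test(base, fj)$p
      })
      expect_equal(row$p, min(ps), tolerance = 1e-10)
      included <- c(included, row$channel)
    }
  }
})

test_that("residual sum of squares is non-increasing along forward steps", {
  set.seed(26)
  x <- matrix(rnorm(18 * 10), 18, 10)
  y <- x %*% c(1, -1, rep(0, 8)) + rnorm(18, sd = 0.3)
  m <- smlr_fit(x, drop(y), p_enter = 0.4, p_remove = 0.5)
  adds <- m$trace[m$trace$action == "add", ]
  if (nrow(adds) > 1) expect_true(all(diff(adds$rss) <= 1e-10))
})

test_that("prediction is the linear form and matches channels by wavelength", {
  set.seed(27)
  x <- matrix(rnorm(12 * 6), 12, 6)
  attr(x, "wavelengths") <- seq(1500, 1600, length.out = 6)
  y <- 4 - 2 * x[, 3]
  m <- smlr_fit(x, y)
  expect_equal(predict(m, x), y, tolerance = 1e-8)

  # intercept-only model predicts a constant
  m0 <- smlr_fit(x, rnorm(12), p_enter = 1e-12, p_remove = 1e-10)
  expect_equal(predict(m0, x), rep(m0$intercept, 12))

  # linearity in the spectra
  x2 <- matrix(rnorm(12 * 6), 12, 6)
  attr(x2, "wavelengths") <- attr(x, "wavelengths")
  a <- 0.3
  mix <- a * x + (1 - a) * x2
  attr(mix, "wavelengths") <- attr(x, "wavelengths")
  expect_equal(predict(m, mix),
               a * predict(m, x) + (1 - a) * predict(m, x2),
               tolerance = 1e-8)

  # missing wavelength -> model mismatch
  bad <- x[, -3]
  attr(bad, "wavelengths") <- attr(x, "wavelengths")[-3]
  expect_error(predict(m, bad), class = "nircal_model_mismatch")
})
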