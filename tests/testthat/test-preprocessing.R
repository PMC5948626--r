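test_that("absorbance conversion is log10(1/x) and rejects nonpositive input", {
  m <- matrix(c(1, 0.01, 200, 10), 2, 2)
  ab <- to_absorbance(m, wavelengths = c(1000, 1500))
  expect_equal(ab$values, log10(1 / m), ignore_attr = TRUE)
  expect_equal(ab$values[1, 1], 0)
  expect_equal(ab$values[2, 1], 2)
  expect_equal(ab$values[1, 2], -log10(200))
  expect_identical(ab$provenance, "absorbance")
  m[2, 2] <- 0
  err <- tryCatch(to_absorbance(m), condition = identity)
  expect_s3_class(err, "nircal_nonpositive_signal")
  expect_match(conditionMessage(err), "2,2")
})

test_that("per-wavelength CV averages per-sample CVs and matches a brute-force oracle", {
  # constant replicates -> zero CV
  ds0 <- list(transflectance = array(5, c(3, 4, 6)),
              wavelengths = 1:6, concentrations = 1:3)
  class(ds0) <- "spectra_dataset"
  expect_equal(cv_per_wavelength(ds0), rep(0, 6))

  # known mean/SD at one channel, identical across samples
  tr <- array(100, c(2, 3, 2))
  tr[, , 2] <- rep(c(90, 100, 110), each = 2)  # mean 100, sd 10
  ds1 <- structure(list(transflectance = tr, wavelengths = 1:2,
                        concentrations = 1:2), class = "spectra_dataset")
  expect_equal(cv_per_wavelength(ds1)[2], 10)

  # random dataset vs double-loop oracle
  set.seed(7)
  tr <- array(abs(rnorm(4 * 5 * 8, 100, 20)) + 1, c(4, 5, 8))
  ds <- structure(list(transflectance = tr, wavelengths = 1:8,
                       concentrations = 1:4), class = "spectra_dataset")
  oracle <- sapply(1:8, function(ch) {
    mean(sapply(1:4, function(i) {
      v <- tr[i, , ch]
      100 * sd(v) / mean(v)
    }))
  })
  expect_equal(cv_per_wavelength(ds), oracle, tolerance = 1e-10)

  tr[1, , 3] <- c(-1, 0, 1, 0, 0)  # zero mean
  dsz <- structure(list(transflectance = tr, wavelengths = 1:8,
                        concentrations = 1:4), class = "spectra_dataset")
  expect_error(cv_per_wavelength(dsz),
               class = "nircal_division_degenerate")
})

test_that("CV band filter removes channels strictly above the mean", {
  bf <- remove_noisy_bands(c(1, 1, 10))
  expect_equal(bf$threshold, 4)
  expect_equal(bf$retained_mask, c(TRUE, TRUE, FALSE))
  # all-equal CVs: nothing removed (strict inequality)
  bf2 <- remove_noisy_bands(rep(3, 5))
  expect_true(all(bf2$retained_mask))
  expect_error(remove_noisy_bands(c(1, NA, 2)),
               class = "nircal_invalid_design")
})

test_that("SNV standardizes rows and is scale/offset invariant and idempotent", {
  ab <- absorbance_matrix(rbind(c(1, 2, 3), c(5, 1, 9)), 1:3)
  s <- snv(ab)
  expect_equal(s$values[1, ], c(-1, 0, 1))
  expect_equal(rowMeans(s$values), c(0, 0))
  expect_equal(apply(s$values, 1, sd), c(1, 1), tolerance = 1e-10)

  set.seed(1)
  x <- matrix(rnorm(10 * 50), 10, 50)
  ab <- absorbance_matrix(x, 1:50)
  s1 <- snv(ab)
  # direct formula oracle
  o <- t(apply(x, 1, function(r) (r - mean(r)) / sd(r)))
  expect_equal(s1$values, o, tolerance = 1e-12)
  # affine invariance (positive slope) and idempotence
  s2 <- snv(absorbance_matrix(2.5 * x + 7, 1:50))
  expect_equal(s2$values, s1$values, tolerance = 1e-8)
  expect_equal(snv(s1)$values, s1$values, tolerance = 1e-8)

  expect_error(snv(absorbance_matrix(rbind(c(1, 1, 1)), 1:3)),
               class = "nircal_degenerate_spectrum")
})

test_that("MSC inverts affine scatter against the reference and is idempotent", {
  set.seed(2)
  ref <- sort(rnorm(40))
  x <- rbind(ref, 3 + 2 * ref, -1 + 0.5 * ref)
  ab <- absorbance_matrix(x, 1:40)
  out <- msc(ab, reference = ref)
  for (i in 1:3) expect_equal(unname(out$values[i, ]), ref,
                              tolerance = 1e-10)
  cf <- attr(out, "msc_coefficients")
  expect_equal(unname(cf[1, ]), c(0, 1), tolerance = 1e-10)
  expect_equal(unname(cf[2, ]), c(3, 2), tolerance = 1e-10)

  # random rows: (a, b) match the normal-equations oracle
  x <- matrix(rnorm(6 * 40), 6, 40)
  ab <- absorbance_matrix(x, 1:40)
  out <- msc(ab)
  ref <- colMeans(x)
  cf <- attr(out, "msc_coefficients")
  for (i in 1:6) {
    ab_or <- solve(rbind(c(length(ref), sum(ref)),
                         c(sum(ref), sum(ref^2))),
                   c(sum(x[i, ]), sum(x[i, ] * ref)))
    expect_equal(unname(cf[i, ]), unname(ab_or), tolerance = 1e-10)
  }
  # idempotence on MSC's target disturbance class: rows that are affine
  # transforms of a common shape are fully corrected in one pass
  shape_v <- sin(seq(0, 3, length.out = 40)) + 0.5
  scat <- t(sapply(1:5, function(i) (0.5 + 0.3 * i) * shape_v + 0.2 * i))
  one <- msc(absorbance_matrix(scat, 1:40))
  two <- msc(one)
  expect_equal(two$values, one$values, tolerance = 1e-8)

  expect_error(msc(absorbance_matrix(matrix(1, 3, 5), 1:5)),
               class = "nircal_uncorrectable_spectrum")
})

test_that("Savitzky-Golay coefficients match the design-matrix definition", {
  expect_equal(sg_coefficients(5, 2, 0), c(-3, 12, 17, 12, -3) / 35,
               tolerance = 1e-12)
  # smoothing coefficients sum to 1; derivative coefficients sum to 0
  expect_equal(sum(sg_coefficients(11, 2, 0)), 1, tolerance = 1e-12)
  expect_equal(sum(sg_coefficients(11, 2, 1)), 0, tolerance = 1e-12)
  expect_error(sg_coefficients(6, 2, 0), class = "nircal_invalid_parameters")
  expect_error(sg_coefficients(5, 5, 0), class = "nircal_invalid_parameters")
  expect_error(sg_coefficients(5, 2, 3), class = "nircal_invalid_parameters")
})

test_that("Savitzky-Golay filtering reproduces polynomials and trims edges", {
  wl <- seq(1000, 1100, length.out = 51)
  # derivative of a linear ramp (slope m per channel) is m everywhere
  m <- 0.37
  x <- rbind(m * seq_len(51), 5 + m * seq_len(51))
  ab <- absorbance_matrix(x, wl)
  d1 <- savitzky_golay(ab, 11, 2, 1)
  expect_equal(ncol(d1$values), 51 - 10)
  expect_equal(d1$wavelengths, wl[6:46])
  expect_true(all(abs(d1$values - m) < 1e-10))

  # degree-2 smoothing is exact on a quadratic
  q <- outer(1:2, (seq_len(51) - 26)^2 * 0.01)
  sm <- savitzky_golay(absorbance_matrix(q, wl), 7, 2, 0)
  expect_equal(sm$values, q[, 4:48], tolerance = 1e-10,
               ignore_attr = TRUE)

  # degree = window - 1 smoothing is the identity on valid channels
  set.seed(3)
  r <- matrix(rnorm(2 * 51), 2, 51)
  idf <- savitzky_golay(absorbance_matrix(r, wl), 5, 4, 0)
  expect_equal(idf$values, r[, 3:49], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("Savitzky-Golay agrees with the signal package on random spectra", {
  skip_if_not_installed("signal")
  set.seed(4)
  x <- matrix(rnorm(3 * 101), 3, 101)
  ab <- absorbance_matrix(x, seq_len(101))
  for (p in list(c(11, 2, 0), c(7, 3, 1), c(9, 4, 2))) {
    ours <- savitzky_golay(ab, p[1], p[2], p[3])
    h <- (p[1] - 1) / 2
    for (i in 1:3) {
      theirs <- signal::sgolayfilt(x[i, ], p = p[2], n = p[1], m = p[3])
      expect_equal(unname(ours$values[i, ]),
                   theirs[(h + 1):(101 - h)], tolerance = 1e-8)
    }
  }
})

test_that("preprocessing operators are row-local (sample permutation equivariance)", {
  set.seed(5)
  x <- matrix(rnorm(6 * 30), 6, 30)
  ab <- absorbance_matrix(x, 1:30)
  perm <- c(4, 1, 6, 2, 5, 3)
  abp <- absorbance_matrix(x[perm, ], 1:30)
  expect_equal(snv(abp)$values, snv(ab)$values[perm, ])
  expect_equal(savitzky_golay(abp, 7, 2, 1)$values,
               savitzky_golay(ab, 7, 2, 1)$values[perm, ])
  # MSC's reference is permutation-invariant, so MSC commutes too
  expect_equal(msc(abp)$values, msc(ab)$values[perm, ])
})
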