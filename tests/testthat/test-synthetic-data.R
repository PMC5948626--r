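test_that("base concentrations are evenly spaced, rounded, and validated", {
  expect_equal(make_base_concentrations(2, 0, 100), c(0, 100))
  expect_equal(make_base_concentrations(3, 0, 10), c(0, 5, 10))
  # the emulated study series, to within the +-1 mg/kg rounding ambiguity
  got <- make_base_concentrations(11, 1017, 2169)
  expect_length(got, 11)
  expect_true(all(abs(got - base_conc_reference) <= 1))
  expect_error(make_base_concentrations(1, 0, 10),
               class = "nircal_invalid_design")
  expect_error(make_base_concentrations(5, 10, 10),
               class = "nircal_invalid_design")
})

test_that("blending interleaves midpoints and preserves the range", {
  expect_equal(blend_consecutive(c(100, 200)), c(100, 150, 200))
  expect_equal(blend_consecutive(7), 7)
  expect_error(blend_consecutive(c(3, 1, 2)),
               class = "nircal_invalid_design")

  for (seed in 1:20) {
    set.seed(seed)
    x <- sort(round(runif(sample(2:9, 1), 0, 3000)))
    b <- blend_consecutive(x)
    expect_length(b, 2 * length(x) - 1)
    expect_false(is.unsorted(b))
    expect_equal(range(b), range(x))       # conservation
    mids <- b[seq(2, length(b) - 1, by = 2)]
    lo <- x[-length(x)]; hi <- x[-1]
    # monotone mixing: strictly between parents (when parents differ)
    differing <- hi - lo > 1
    expect_true(all(mids[differing] > lo[differing] &
                      mids[differing] < hi[differing]))
    expect_true(all(abs(mids - (lo + hi) / 2) <= 0.5))
  }
})

test_that("generator is seed-deterministic and respects its config", {
  cfg <- fixture_default(11)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a, b)
  c2 <- generate_dataset(fixture_default(12))
  expect_false(identical(a$dataset$transflectance,
                         c2$dataset$transflectance))

  ds <- a$dataset
  expect_equal(dim(ds$transflectance), c(21, 10, 921))
  expect_true(all(ds$transflectance > 0))
  expect_equal(length(ds$concentrations), 21)
  expect_true(all(abs(ds$concentrations - blended_conc_reference) <= 1))

  # planted channel sets are within the grid and disjoint
  tr <- a$truth
  expect_true(all(tr$planted_informative_channels %in% seq_len(921)))
  expect_length(intersect(tr$planted_informative_channels,
                          tr$planted_noisy_channels), 0)
})

test_that("mean transflectance hits the power target at 1600 nm", {
  for (target in c(200, 300, 400)) {
    out <- generate_dataset(fixture_default(3, power_target = target))
    ds <- out$dataset
    ref <- which.min(abs(ds$wavelengths - 1600))
    got <- mean(ds$transflectance[, , ref])
    # within 3x the between-acquisition spread seen in such setups
    expect_lt(abs(got - target), 3 * 3.38)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(wavelength_grid = c(1000, 900)),
               class = "nircal_invalid_design")
  expect_error(generator_config(wavelength_grid = seq(800, 2600, 2)),
               class = "nircal_invalid_design")
  expect_error(generator_config(conc_min = 2000, conc_max = 1000),
               class = "nircal_invalid_design")
  expect_error(generator_config(informative_band_centers = c(1830, 2700)),
               class = "nircal_invalid_design")
  expect_error(generator_config(noise_sd_clean = 5, noise_sd_noisy = 2),
               class = "nircal_invalid_design")
})

test_that("noise SD is elevated inside the noisy band by the configured ratio", {
  # Monte-Carlo estimate over many acquisitions of one sample
  cfg <- generator_config(seed = 5, n_base_samples = 2, blend = FALSE,
                          n_acquisitions = 50,
                          scatter_slope_sd = 0, scatter_offset_sd = 0)
  ds <- generate_dataset(cfg)$dataset
  st <- replicate_statistics(ds)
  noisy <- ds$wavelengths >= 2240 & ds$wavelengths <= 2600
  ratio <- mean(st$sd[, noisy]) / mean(st$sd[, !noisy])
  expect_gt(ratio, 10 * 0.8)
  expect_lt(ratio, 10 * 1.2)
})

test_that("planted signal is affine in concentration when noise vanishes", {
  # lossless optical path: the hardware-loss term subtracts a constant in
  # power, which is a (small) log-curvature in absorbance
  cfg <- generator_config(seed = 9, noise_sd_clean = 1e-9,
                          noise_sd_noisy = 1e-8,
                          scatter_slope_sd = 0, scatter_offset_sd = 0,
                          loss_fraction = 0,
                          n_acquisitions = 2)
  out <- generate_dataset(cfg)
  ds <- out$dataset
  ab <- to_absorbance(average_acquisitions(ds))
  for (j in out$truth$informative_center_channels) {
    fit <- stats::lm(ab$values[, j] ~ ds$concentrations)
    expect_gt(summary(fit)$r.squared, 1 - 1e-8)
  }
})

test_that("replicate statistics match a two-pass oracle and use n-1", {
  cfg <- generator_config(seed = 21, n_base_samples = 3, blend = FALSE,
                          wavelength_grid = seq(900, 2600, length.out = 41),
                          n_acquisitions = 4)
  ds <- generate_dataset(cfg)$dataset
  st <- replicate_statistics(ds)
  for (i in 1:3) {
    for (j in c(1, 17, 41)) {
      v <- ds$transflectance[i, , j]
      expect_equal(st$mean[i, j], sum(v) / length(v))
      expect_equal(st$sd[i, j],
                   sqrt(sum((v - mean(v))^2) / (length(v) - 1)))
    }
  }
  # hand example: replicates {1,2,3} -> mean 2, sd 1
  dd <- ds
  dd$transflectance <- array(rep(1:3, each = 1), c(1, 3, 1))
  st2 <- replicate_statistics(dd)
  expect_equal(unname(st2$mean[1, 1]), 2)
  expect_equal(unname(st2$sd[1, 1]), 1)

  one <- ds
  one$transflectance <- ds$transflectance[, 1, , drop = FALSE]
  expect_error(replicate_statistics(one),
               class = "nircal_insufficient_replicates")
})
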