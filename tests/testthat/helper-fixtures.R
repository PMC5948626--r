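# Shared fixtures: generator configurations used across tests.
# All datasets are generated in code at test time; nothing is stored.

# Polyphenol concentrations of the emulated study design (mg/kg): the 11
# base oils and the 21-sample blended series.
base_conc_reference <- c(1017, 1132, 1247, 1362, 1478, 1593, 1708, 1823,
                         1939, 2054, 2169)
blended_conc_reference <- c(1017, 1074, 1132, 1189, 1247, 1305, 1362, 1420,
                            1478, 1535, 1593, 1650, 1708, 1766, 1823, 1881,
                            1939, 1996, 2054, 2112, 2169)

# Default study conditions: 21 blended samples, 10 acquisitions, 400 ut
# target, 10x white noise in the 2240-2600 nm band.
fixture_default <- function(seed, ...) {
  generator_config(seed = seed, ...)
}

# Recovery fixture: high-SNR structured conditions (see ?study_config).
fixture_recovery <- function(seed) study_config("structured", seed = seed)

# Noisy fixture: dominant white detector noise, for the acquisition-count
# and lamp-power studies.
fixture_noisy <- function(seed, power_target = 400) {
  study_config("noisy", seed = seed, power_target = power_target)
}

# Small matched (spectra, response) pair for regression-level tests.
small_design <- function(n = 12, m = 4, seed = 42) {
  set.seed(seed)
  x <- matrix(rnorm(n * m), n, m)
  beta <- seq_len(m)
  y <- drop(2 + x %*% beta + rnorm(n, sd = 0.1))
  list(x = x, y = y, beta = beta)
}
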