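## Synthetic transflectance spectra with the statistical structure of a
## blended-sample olive-oil calibration study: evenly spaced base
## concentrations, pairwise blends, replicate acquisitions per sample,
## lamp-power groups referenced at 1600 nm, concentration-linked absorption
## features, a low-SNR detector band, and per-acquisition scatter.

#' Evenly spaced base concentrations
#'
#' Builds the ground-truth polyphenol concentrations of the base sample set:
#' `n` values evenly spaced from `c_min` to `c_max` inclusive, rounded
#' half-away-from-zero to integer mg/kg (concentrations are reported as
#' integers in this domain).
#'
#' @param n Number of base samples (at least 2).
#' @param c_min,c_max Concentration range in mg/kg, `c_min < c_max`.
#' @return Numeric vector of length `n`, integer-valued mg/kg.
#' @examples
#' make_base_concentrations(11, 1017, 2169)
#' @export
make_base_concentrations <- function(n, c_min, c_max) {
  if (!is_count(n) || n < 2) {
    stop_nircal("invalid design: need at least 2 base samples (got %s)",
                format(n), class = "nircal_invalid_design")
  }
  if (!is.numeric(c_min) || !is.numeric(c_max) || c_min >= c_max) {
    stop_nircal("invalid design: require c_min < c_max (got %s >= %s)",
                format(c_min), format(c_max), class = "nircal_invalid_design")
  }
  round_half_away(seq(c_min, c_max, length.out = n))
}

#' Pairwise blending of consecutive samples
#'
#' Emulates blending equal volumes of oils with consecutive concentrations:
#' the output interleaves the originals with the midpoints of consecutive
#' pairs (rounded to integer mg/kg), growing `n` samples to `2n - 1`.
#'
#' @param concentrations Sorted (ascending) concentration vector in mg/kg.
#' @return Sorted numeric vector of length `2 * length(concentrations) - 1`.
#' @examples
#' blend_consecutive(c(100, 200))
#' @export
blend_consecutive <- function(concentrations) {
  if (length(concentrations) < 1L || anyNA(concentrations)) {
    stop_nircal("invalid design: empty or missing concentrations",
                class = "nircal_invalid_design")
  }
  if (is.unsorted(concentrations, strictly = FALSE)) {
    stop_nircal("invalid design: concentrations must be sorted ascending",
                class = "nircal_invalid_design")
  }
  n <- length(concentrations)
  if (n == 1L) return(concentrations)
  mid <- round_half_away((concentrations[-n] + concentrations[-1L]) / 2)
  out <- numeric(2L * n - 1L)
  out[seq(1L, 2L * n - 1L, by = 2L)] <- concentrations
  out[seq(2L, 2L * n - 2L, by = 2L)] <- mid
  out
}

#' Configuration of the synthetic spectra generator
#'
#' Collects every knob of the generative model. The defaults describe the
#' emulated study design: 11 base oils evenly spanning 1017--2169 mg/kg,
#' blended pairwise to 21 samples; 10 acquisitions per sample; a 921-channel
#' wavelength grid uniform over 900--2600 nm; a lamp/detector response
#' peaking at the 1600 nm transflectance maximum with the received power
#' scaled to `power_target` (one of 200/300/400 ut) at that reference
#' wavelength; concentration-linked absorption features near 1830, 1917 and
#' 2189 nm; a low-SNR band over 2240--2600 nm whose additive detector noise
#' is `noise_sd_noisy` instead of `noise_sd_clean`; and per-acquisition
#' multiplicative/additive scatter in the absorbance domain.
#'
#' Each informative feature is modelled as an absorption shoulder: a
#' Gaussian-CDF step of width `informative_band_widths` (the sigma of the
#' underlying Gaussian, in nm) centred at the quoted wavelength, so the
#' first derivative of the feature is a Gaussian peaking exactly at the
#' centre. The feature amplitude is
#' `strength * (concentration + interferent)`, where the per-sample,
#' per-band interferent (SD `interferent_sd`, in equivalent mg/kg)
#' represents co-absorbing minor compounds; interferent absorbance uses a
#' broader shoulder (`interferent_width_factor` times wider), as background
#' absorbers in this spectral region are broader than the analyte feature.
#' `interferent_sd = 0` (the default) gives a noise-free concentration
#' signal at the band centres.
#'
#' @param n_base_samples Number of base oils before blending.
#' @param conc_min,conc_max Base concentration range, mg/kg.
#' @param blend Blend consecutive pairs to `2n - 1` samples?
#' @param wavelength_grid Strictly increasing grid in nm within
#'   \[900, 2600\].
#' @param n_acquisitions Replicate acquisitions per sample.
#' @param power_target Received power target at the reference wavelength,
#'   in raw detector units ("ut").
#' @param reference_wavelength Reference wavelength for the power target, nm.
#' @param informative_band_centers Centres of the concentration-linked
#'   features, nm.
#' @param informative_band_widths Feature width (Gaussian sigma), nm;
#'   recycled over bands.
#' @param informative_band_strengths Absorbance per mg/kg at full feature
#'   amplitude; recycled over bands.
#' @param interferent_sd Per-sample, per-band co-absorber amplitude SD in
#'   equivalent mg/kg (0 disables interferents).
#' @param interferent_comp_sd SD (equivalent mg/kg) of an additional
#'   compositional interferent: per-sample band amplitudes constrained to
#'   sum to zero across the bands, emulating competing minor compounds
#'   whose total is roughly fixed while their composition varies
#'   (0 disables).
#' @param interferent_width_factor Width of the interferent shoulder
#'   relative to the analyte feature.
#' @param nuisance_offsets Offsets (nm) of nuisance co-absorber shoulders
#'   flanking every analyte feature; each has its own per-sample amplitude.
#'   `numeric(0)` (the default) disables them.
#' @param nuisance_width_factor Width of the nuisance shoulders relative to
#'   the analyte feature.
#' @param nuisance_sd Per-sample amplitude SD of each nuisance shoulder, in
#'   equivalent mg/kg.
#' @param background_absorbance Flat baseline absorbance of the oil matrix.
#' @param background_shape Function of wavelength (nm) giving the
#'   nonnegative lamp/detector spectral response, peaking at 1600 nm; it is
#'   rescaled internally to meet `power_target`.
#' @param noisy_band Length-2 nm interval with degraded SNR.
#' @param noise_sd_clean,noise_sd_noisy Additive white detector noise SD
#'   (ut) outside/inside `noisy_band`; the noisy value must exceed the
#'   clean one.
#' @param noise_smooth_sd SD (ut) of an additional spectrally smooth
#'   per-acquisition noise component (optical/thermal fluctuations,
#'   correlated across neighbouring channels); 0 disables.
#' @param noise_smooth_length Correlation length (nm, Gaussian kernel SD)
#'   of the smooth noise component.
#' @param scatter_slope_sd SD of the per-acquisition multiplicative
#'   absorbance disturbance (around 1).
#' @param scatter_offset_sd SD of the per-acquisition additive absorbance
#'   baseline offset.
#' @param drift_sd SD of the per-acquisition amplitudes of three smooth
#'   baseline modes (a linear tilt plus two low-order sinusoids across the
#'   grid, each of unit peak amplitude), emulating slow lamp
#'   colour-temperature and probe-coupling drift between acquisitions
#'   (0 disables).
#' @param loss_fraction Fraction of transmitted power lost to hardware
#'   (connectors, multiplexing) at every wavelength.
#' @param seed Integer seed; identical configurations with identical seeds
#'   generate identical datasets.
#' @return An object of class `generator_config` (a validated list).
#' @seealso [generate_dataset()]
#' @export
generator_config <- function(n_base_samples = 11,
                             conc_min = 1017,
                             conc_max = 2169,
                             blend = TRUE,
                             wavelength_grid = seq(900, 2600,
                                                   length.out = 921),
                             n_acquisitions = 10,
                             power_target = 400,
                             reference_wavelength = 1600,
                             informative_band_centers = c(1830, 1917, 2189),
                             informative_band_widths = 15,
                             informative_band_strengths = 2e-4,
                             interferent_sd = 0,
                             interferent_comp_sd = 0,
                             interferent_width_factor = 1,
                             nuisance_offsets = numeric(0),
                             nuisance_width_factor = 2,
                             nuisance_sd = 0,
                             background_absorbance = 0.15,
                             background_shape = function(wl)
                               exp(-((wl - 1600) / 700)^2),
                             noisy_band = c(2240, 2600),
                             noise_sd_clean = 1,
                             noise_sd_noisy = 10,
                             noise_smooth_sd = 0,
                             noise_smooth_length = 30,
                             scatter_slope_sd = 0.01,
                             scatter_offset_sd = 0.005,
                             drift_sd = 0,
                             loss_fraction = 0.02,
                             seed = 1L) {
  cfg <- list(n_base_samples = n_base_samples, conc_min = conc_min,
              conc_max = conc_max, blend = isTRUE(blend),
              wavelength_grid = as.numeric(wavelength_grid),
              n_acquisitions = n_acquisitions, power_target = power_target,
              reference_wavelength = reference_wavelength,
              informative_band_centers = as.numeric(informative_band_centers),
              informative_band_widths =
                rep_len(informative_band_widths,
                        length(informative_band_centers)),
              informative_band_strengths =
                rep_len(informative_band_strengths,
                        length(informative_band_centers)),
              interferent_sd = interferent_sd,
              interferent_comp_sd = interferent_comp_sd,
              interferent_width_factor = interferent_width_factor,
              nuisance_offsets = as.numeric(nuisance_offsets),
              nuisance_width_factor = nuisance_width_factor,
              nuisance_sd = nuisance_sd,
              background_absorbance = background_absorbance,
              background_shape = background_shape,
              noisy_band = as.numeric(noisy_band),
              noise_sd_clean = noise_sd_clean,
              noise_sd_noisy = noise_sd_noisy,
              noise_smooth_sd = noise_smooth_sd,
              noise_smooth_length = noise_smooth_length,
              scatter_slope_sd = scatter_slope_sd,
              scatter_offset_sd = scatter_offset_sd,
              drift_sd = drift_sd,
              loss_fraction = loss_fraction,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

#' @noRd
validate_generator_config <- function(cfg) {
  wl <- cfg$wavelength_grid
  if (length(wl) < 2L || any(diff(wl) <= 0)) {
    stop_nircal("invalid design: wavelength grid must be strictly increasing",
                class = "nircal_invalid_design")
  }
  if (min(wl) < 900 || max(wl) > 2600) {
    stop_nircal("invalid design: wavelength grid must lie within [900, 2600] nm",
                class = "nircal_invalid_design")
  }
  if (cfg$conc_min >= cfg$conc_max) {
    stop_nircal("invalid design: conc_min must be below conc_max",
                class = "nircal_invalid_design")
  }
  ctr <- cfg$informative_band_centers
  if (any(ctr < min(wl)) || any(ctr > max(wl))) {
    stop_nircal("invalid design: band center outside the wavelength grid (%s nm)",
                paste(ctr[ctr < min(wl) | ctr > max(wl)], collapse = ", "),
                class = "nircal_invalid_design")
  }
  if (!(cfg$noise_sd_noisy > cfg$noise_sd_clean)) {
    stop_nircal("invalid design: noise_sd_noisy must exceed noise_sd_clean",
                class = "nircal_invalid_design")
  }
  if (!is_count(cfg$n_acquisitions)) {
    stop_nircal("invalid design: n_acquisitions must be a positive integer",
                class = "nircal_invalid_design")
  }
  if (!is.function(cfg$background_shape)) {
    stop_nircal("invalid design: background_shape must be a function of nm",
                class = "nircal_invalid_design")
  }
  invisible(cfg)
}

## Noiseless absorbance of sample with concentration `conc` and per-band
## interferent amplitudes `eta` (equivalent mg/kg), over the grid.
#' @noRd
ideal_absorbance <- function(cfg, conc, eta = NULL, nu = NULL) {
  wl <- cfg$wavelength_grid
  a <- rep(cfg$background_absorbance, length(wl))
  for (b in seq_along(cfg$informative_band_centers)) {
    ctr <- cfg$informative_band_centers[b]
    sig <- cfg$informative_band_widths[b]
    s <- cfg$informative_band_strengths[b]
    a <- a + s * conc * stats::pnorm(wl, ctr, sig)
    if (!is.null(eta) && eta[b] != 0) {
      a <- a + s * eta[b] *
        stats::pnorm(wl, ctr, sig * cfg$interferent_width_factor)
    }
    if (!is.null(nu)) {
      for (j in seq_along(cfg$nuisance_offsets)) {
        if (nu[b, j] != 0) {
          a <- a + s * nu[b, j] *
            stats::pnorm(wl, ctr + cfg$nuisance_offsets[j],
                         sig * cfg$nuisance_width_factor)
        }
      }
    }
  }
  a
}

#' Generate a synthetic spectra dataset
#'
#' Simulates the full acquisition design described in
#' [generator_config()]. For every sample and acquisition the absorbance
#' spectrum is built as (features scaled by concentration and interferents)
#' + flat background, perturbed by a per-acquisition affine scatter
#' disturbance `b * A + a`; received power then follows the energy balance
#' `P_r = P_t - P_abs - L`, with `P_t` the lamp/detector response,
#' `P_abs = P_t * (1 - 10^-A)` the absorbed power and `L` a fixed fractional
#' hardware loss, plus additive detector noise whose SD is elevated inside
#' the configured noisy band. `P_t` is scaled once per dataset so the
#' noiseless mean received power at the reference wavelength equals
#' `power_target`. Values are floored at `1e-6` ut so absorbance
#' (`log10(1/x)`) stays defined.
#'
#' @param config A [generator_config()].
#' @return A list with components `dataset` (a `spectra_dataset`: 3-axis
#'   array `transflectance[sample, acquisition, channel]` in ut,
#'   `wavelengths`, `concentrations`, `metadata`) and `truth` (a
#'   `ground_truth`: planted informative/noisy channel indices, the channel
#'   nearest each band centre, per-acquisition scatter parameters and
#'   per-sample interferent amplitudes).
#' @examples
#' out <- generate_dataset(generator_config(seed = 7))
#' dim(out$dataset$transflectance)
#' @export
generate_dataset <- function(config) {
  cfg <- validate_generator_config(config)
  wl <- cfg$wavelength_grid
  nwl <- length(wl)

  conc <- make_base_concentrations(cfg$n_base_samples, cfg$conc_min,
                                   cfg$conc_max)
  if (cfg$blend) conc <- blend_consecutive(conc)
  nsamp <- length(conc)
  nacq <- cfg$n_acquisitions

  noisy_mask <- wl >= cfg$noisy_band[1] & wl <= cfg$noisy_band[2]
  noise_sd <- ifelse(noisy_mask, cfg$noise_sd_noisy, cfg$noise_sd_clean)

  shape <- cfg$background_shape(wl)
  if (any(shape < 0)) {
    stop_nircal("invalid design: background_shape must be nonnegative",
                class = "nircal_invalid_design")
  }
  ref_idx <- which.min(abs(wl - cfg$reference_wavelength))

  out <- with_seed(cfg$seed, {
    nb <- length(cfg$informative_band_centers)
    eta <- if (cfg$interferent_sd > 0) {
      matrix(stats::rnorm(nsamp * nb, sd = cfg$interferent_sd), nsamp, nb)
    } else {
      matrix(0, nsamp, nb)
    }
    if (cfg$interferent_comp_sd > 0 && nb >= 2) {
      z <- matrix(stats::rnorm(nsamp * nb, sd = cfg$interferent_comp_sd),
                  nsamp, nb)
      ## project onto the zero-sum (compositional) subspace
      eta <- eta + z - rowMeans(z)
    }
    nnu <- length(cfg$nuisance_offsets)
    nu <- if (nnu > 0 && cfg$nuisance_sd > 0) {
      array(stats::rnorm(nsamp * nb * nnu, sd = cfg$nuisance_sd),
            c(nsamp, nb, nnu))
    } else {
      array(0, c(nsamp, nb, max(nnu, 1L)))
    }
    ideal <- t(vapply(seq_len(nsamp),
                      function(i) ideal_absorbance(cfg, conc[i], eta[i, ],
                                                   matrix(nu[i, , ], nb)),
                      numeric(nwl)))

    ## lamp gain: noiseless mean received power at the reference channel
    ## equals the target
    mean_trans_ref <- mean(10^(-ideal[, ref_idx]) - cfg$loss_fraction)
    gain <- cfg$power_target / (shape[ref_idx] * mean_trans_ref)
    pt <- gain * shape

    a_off <- matrix(stats::rnorm(nsamp * nacq, sd = cfg$scatter_offset_sd),
                    nsamp, nacq)
    b_mul <- matrix(stats::rnorm(nsamp * nacq, mean = 1,
                                 sd = cfg$scatter_slope_sd),
                    nsamp, nacq)
    u <- (wl - min(wl)) / diff(range(wl))
    drift_modes <- cbind(u - 0.5, sin(2 * pi * u), sin(4 * pi * u))
    drift <- if (cfg$drift_sd > 0) {
      array(stats::rnorm(nsamp * nacq * 3, sd = cfg$drift_sd),
            c(nsamp, nacq, 3))
    } else {
      array(0, c(nsamp, nacq, 3))
    }

    ## smooth-noise kernel: Gaussian in channels, unit output variance
    smooth_kernel <- NULL
    if (cfg$noise_smooth_sd > 0) {
      step <- mean(diff(wl))
      half <- max(1L, ceiling(3 * cfg$noise_smooth_length / step))
      k <- stats::dnorm(seq(-half, half), sd = cfg$noise_smooth_length / step)
      smooth_kernel <- k / sqrt(sum(k^2))
    }

    trans <- array(NA_real_, c(nsamp, nacq, nwl))
    for (i in seq_len(nsamp)) {
      for (j in seq_len(nacq)) {
        aa <- b_mul[i, j] * ideal[i, ] + a_off[i, j] +
          drop(drift_modes %*% drift[i, j, ])
        pr <- pt * (10^(-aa) - cfg$loss_fraction) +
          stats::rnorm(nwl, sd = noise_sd)
        if (!is.null(smooth_kernel)) {
          half <- (length(smooth_kernel) - 1L) / 2L
          w <- stats::rnorm(nwl + 2L * half)
          sm <- stats::filter(w, smooth_kernel, sides = 2L)
          pr <- pr + cfg$noise_smooth_sd *
            as.numeric(sm[(half + 1L):(half + nwl)])
        }
        trans[i, j, ] <- pmax(pr, 1e-6)
      }
    }
    list(trans = trans, eta = eta, nu = nu, a_off = a_off, b_mul = b_mul,
         drift = drift, gain = gain)
  })

  centers_idx <- vapply(cfg$informative_band_centers,
                        function(ctr) which.min(abs(wl - ctr)), integer(1))
  informative <- sort(unique(unlist(lapply(seq_along(centers_idx), function(b) {
    which(abs(wl - cfg$informative_band_centers[b]) <=
            cfg$informative_band_widths[b])
  }))))

  dataset <- structure(
    list(transflectance = out$trans,
         wavelengths = wl,
         concentrations = conc,
         metadata = list(power_target = cfg$power_target,
                         reference_wavelength = cfg$reference_wavelength,
                         seed = cfg$seed,
                         grid = "uniform-nm",
                         gain = out$gain)),
    class = "spectra_dataset")
  truth <- structure(
    list(planted_informative_channels = informative,
         planted_noisy_channels = which(noisy_mask),
         informative_center_channels = centers_idx,
         scatter_offsets = out$a_off,
         scatter_slopes = out$b_mul,
         drift_amplitudes = out$drift,
         interferents = out$eta,
         nuisance_amplitudes = out$nu),
    class = "ground_truth")

  list(dataset = dataset, truth = truth)
}

#' @export
print.spectra_dataset <- function(x, ...) {
  d <- dim(x$transflectance)
  cat(sprintf(paste0("<spectra_dataset> %d samples x %d acquisitions x %d",
                     " channels (%.0f-%.0f nm), power target %s ut\n"),
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              format(x$metadata$power_target)))
  cat(sprintf("  concentrations: %.0f-%.0f mg/kg\n",
              min(x$concentrations), max(x$concentrations)))
  invisible(x)
}

#' Per-sample replicate statistics
#'
#' Mean and standard deviation (unbiased, `n - 1` denominator) of the
#' transflectance across acquisitions, per sample and channel.
#'
#' @param dataset A `spectra_dataset` with at least 2 acquisitions.
#' @return List of two `samples x channels` matrices, `mean` and `sd`.
#' @export
replicate_statistics <- function(dataset) {
  tr <- dataset$transflectance
  if (length(dim(tr)) != 3L || dim(tr)[2] < 2L) {
    stop_nircal("insufficient replicates: need at least 2 acquisitions per sample",
                class = "nircal_insufficient_replicates")
  }
  m <- apply(tr, c(1, 3), mean)
  s <- apply(tr, c(1, 3), stats::sd)
  list(mean = m, sd = s)
}

#' Preset study configurations
#'
#' Named [generator_config()] presets for the emulated study:
#' \describe{
#'   \item{`"default"`}{The plain acquisition design: clean 1 ut / noisy
#'     10 ut white detector noise, no chemical interference. Used for the
#'     noisy-band screening study.}
#'   \item{`"structured"`}{High-SNR chemometric conditions: the three
#'     absorption shoulders carry the concentration signal, disturbed by
#'     same-shape minor-compound interferents (110 mg/kg equivalent), a
#'     compositional (zero-sum) interferent component (150 mg/kg), and
#'     spectrally smooth detector noise (22 ut, 30 nm correlation length)
#'     over a wide lamp profile. Used for planted-feature recovery.}
#'   \item{`"noisy"`}{The structured design with dominant white detector
#'     noise (8 ut clean / 80 ut noisy), so replicate averaging and lamp
#'     power visibly change the calibration error. Used for the
#'     acquisition-count and lamp-power studies.}
#' }
#' The reasoning behind each constant is laid out in the methods vignette.
#'
#' @param type Preset name.
#' @param seed Integer seed.
#' @param power_target Received-power target in ut (default 400).
#' @return A [generator_config()].
#' @export
study_config <- function(type = c("default", "structured", "noisy"),
                         seed = 1L, power_target = 400) {
  type <- match.arg(type)
  wide_lamp <- function(wl) exp(-((wl - 1600) / 1000)^2)
  switch(type,
         default = generator_config(seed = seed,
                                    power_target = power_target),
         structured = generator_config(
           seed = seed, power_target = power_target,
           informative_band_widths = 6,
           informative_band_strengths = c(5e-5, 6.5e-5, 1e-4),
           background_shape = wide_lamp,
           interferent_sd = 110,
           interferent_comp_sd = 150,
           noise_smooth_sd = 22,
           noise_smooth_length = 30,
           noise_sd_clean = 0.5,
           noise_sd_noisy = 50),
         noisy = generator_config(
           seed = seed, power_target = power_target,
           informative_band_widths = 6,
           informative_band_strengths = c(5e-5, 6.5e-5, 1e-4),
           background_shape = wide_lamp,
           interferent_sd = 60,
           interferent_comp_sd = 100,
           noise_sd_clean = 8,
           noise_sd_noisy = 80))
}
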