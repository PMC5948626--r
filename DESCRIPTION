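Package: nircal
Title: NIR Chemometric Calibration of Polyphenol Content in Olive Oil
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building and validating near-infrared (NIR)
    calibration models of total polyphenol content in virgin olive oil.
    Provides a seeded generator of synthetic transflectance spectra that
    emulates a blended-sample study design with lamp-power groups and a
    low-gain noisy detector band; spectral preprocessing (absorbance
    conversion, standard normal variate, multiplicative scatter
    correction, Savitzky-Golay smoothing and derivatives); coefficient-of-
    variation screening of noisy spectral bands; one-way ANOVA wavelength
    filtering; stepwise multilinear regression with partial F-tests; and
    leave-one-out and random-holdout validation reporting RMSEC/RMSEV and
    calibration/validation R-squared. Acquisition-parameter studies (lamp
    power, number of averaged acquisitions, Savitzky-Golay window sweep)
    are included as reproducible experiment drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    signal,
    withr,
    optparse
Config/testthat/edition: 3
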