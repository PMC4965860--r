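Package: teaspec
Title: Chemometric Quantification of Mineral Adulterants in Tea from FT-IR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for quantifying talcum-powder
    adulteration in tea powder from Fourier-transform infrared (FT-IR)
    transmission spectra. Provides a synthetic-spectra generator with a
    Beer-Lambert dose response, multiplicative scatter, baseline drift and
    additive noise; spectral trimming and preprocessing (moving-average
    smoothing, max-normalization, standard normal variate); NIPALS partial
    least squares regression with leave-one-out cross-validation and the
    usual calibration metrics (R and RMSE for calibration, cross-validation
    and prediction); a hybrid wavenumber-selection cascade of backward
    interval PLS, competitive adaptive reweighted sampling and the
    successive projections algorithm; and extreme learning machine
    regression with a hidden-node sweep. All results are returned as
    tibbles with broom-style tidy()/glance() methods and ggplot2 autoplot()
    support.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
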