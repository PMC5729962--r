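Package: perfopt
Title: Dual-Mode Diffuse Optical Perfusion Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational core of a dual-mode diffuse optical perfusion
    monitor for free-tissue-flap surveillance. Implements diffuse correlation
    spectroscopy analysis (photon time-tag binning, FFT, multitau and direct
    intensity autocorrelation estimators, logarithmic downsampling, and the
    robust plateau-pair tau-half blood-flow surrogate), Monte Carlo photon
    transport in semi-infinite tissue to build probe-specific reflectance
    lookup tables, lookup-table spectral inversion for tissue oxygen
    saturation and total hemoglobin, synthetic generators for photon streams,
    spectra and occlusion/failure experiments, and an end-to-end pipeline that
    computes baseline-referenced responses and classifies arterial versus
    venous vascular compromise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
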