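Package: spectransfer
Title: Calibration Transfer and Hybrid Modelling for NIR Hyperspectral
    Prediction of Microbial Load
Version: 0.1.0
Authors@R:
    person("Spectral", "Maintainer", email = "maintainer@spectransfer.org",
           role = c("aut", "cre"))
Description: Chemometric toolkit for predicting log10 total viable count
    (TVC) from near-infrared hyperspectral reflectance of heterogeneous
    food samples measured in two physical forms (crushed and intact).
    Provides ENVI cube reading and reflectance calibration, region-of-
    interest spectrum extraction, multiplicative scatter correction (MSC),
    competitive adaptive reweighted sampling (CARS) wavelength screening
    with a partial least squares engine, Kennard-Stone and SPXY standard
    sample selection, direct standardization (DS) calibration transfer via
    a truncated-SVD pseudoinverse, epsilon-SVR regression with seeded
    cross-validated tuning, the RMSE/RPD/RER metric suite, hybrid
    calibration-set augmentation, plate-count microbiology helpers, a
    synthetic paired-form data generator, and a scriptable pipeline runner.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
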