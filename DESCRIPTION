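Package: lssclass
Title: Tissue Characterization from Light-Scattering Spectra with 1D
    Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying layered cardiac tissue constructs from
    broad-band light-scattering (diffuse reflectance) spectra. Provides
    spectral preprocessing (mean normalization, reflectance-standard
    calibration, Gaussian-smoothed difference curves, signal-to-noise
    estimation), an algebra for binary construct labels describing stacks
    of 200 micrometre tissue sections, a seeded forward simulator of
    layered-tissue spectra with depth-dependent fiber sensitivity and
    subject-level variability, a compact one-dimensional convolutional
    neural network trained under a subject-wise hold-out protocol, an
    ordinal proximal-credit accuracy statistic, and ranking of single and
    paired collection fibers by classification accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
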