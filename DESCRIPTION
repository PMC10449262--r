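Package: octoprops
Title: Depth-Resolved Attenuation and Backscattering Estimation for
    Optical Coherence Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint depth-resolved estimation of the optical attenuation
    coefficient and the backscattering fraction from OCT A-scan intensity
    using a constrained stationary iteration with adaptive piecewise-constant
    regularization of the backscattering profile.  Includes a closed-form
    single-scattering A-line simulator for layered phantoms, a Monte Carlo
    photon-transport engine for layered tissue with coherence-gated A-line
    synthesis, axial point-spread-function calibration by exhaustive search,
    noise-floor fitting and exponential tail extrapolation, and an
    attenuation-compensated intensity renderer.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
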