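Package: ctdr
Title: Robustness of Proton Dose Distributions to CT Resolution and Noise
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how proton-therapy dose distributions respond
    to degradation of the planning CT. Provides synthetic anatomical and wire
    resolution phantoms, mm-exact boxcar and truncated-Gaussian low-pass
    filtering with additive white Gaussian noise, an analytic proton
    pencil-beam dose engine with water-equivalent-thickness ray tracing and
    spread-out Bragg peak construction, minimax robust optimization of spot
    weights over setup-shift and density scenarios, a global 3D gamma-index
    comparison with a brute-force oracle, scenario-based robustness metrics
    (worst-case and voxel-wise-minimum V95, the D-at-50-percent-of-scenarios
    statistic), line-spread-function and MTF metrology, and an algebraic
    noise-resolution-exposure model for estimating x-ray exposure sparing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    pracma,
    rlang,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
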