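Package: kcoverage
Title: Joint Optimization of MRI k-Space Coverage, Signal Averaging, and
    Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing SNR-efficient Cartesian MRI acquisitions by
    jointly optimizing the k-space grid size, the per-phase-encode signal
    averaging pattern, and the parameters of the downstream
    denoising/reconstruction method under a fixed scan-time budget. Implements
    a bilevel design search (inner joint optimization of reconstruction
    parameters and averaging pattern per candidate grid size, outer brute-force
    selection of the grid size against high-resolution references), apodized
    Fourier reconstruction, SENSE reconstruction with total-variation
    regularization solved by ADMM, Euclidean projection onto the scan-time
    budget, globally optimal greedy integer rounding of averaging patterns, a
    multicoil brain-like phantom generator with SNR calibration, and NRMSE/SSIM
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
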