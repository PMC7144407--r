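Package: regnet
Title: Regularizing Networks for Ill-Posed Linear Inverse Problems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classical filter-based regularization of ill-posed linear inverse
    problems (Tikhonov, truncated SVD) augmented by trained networks: null-space
    networks that add learned components invisible to the forward operator, and
    a data-driven continued SVD that extends truncated singular components from
    the retained ones. Includes the full finite-dimensional spectral machinery
    (singular systems, spectral filters, qualification estimation, source
    elements), a sparse-view Radon transform discretized with Kaiser-Bessel
    blob basis functions with analytically known projections, seeded
    Shepp-Logan-type phantom generation and sinogram simulation, a small
    from-scratch convolutional encoder-decoder trained by stochastic gradient
    descent, and numerical verification of the regularization theory
    (distance functions, error-bound decompositions, convergence rates).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    png,
    yaml
Config/testthat/edition: 3
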