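Package: bayespose
Title: Bayesian Orientation Estimation for Cryo-EM and Cryo-ET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Orientation determination of a rigid rotation relating a noisy
    observation (a 2D polar image, a 2D tomographic projection, or a 3D
    subtomogram) to a reference structure. Implements the Bayesian
    minimum-mean-square-error (MMSE) rotation estimator -- the posterior-mean
    rotation matrix projected onto SO(3) by orthogonal Procrustes -- together
    with the maximum-likelihood (MLE) and maximum-a-posteriori (MAP) grid
    estimators, isotropic Gaussian priors on SO(3), quadrature discretizations
    of the rotation group, the soft-assignment expectation-maximization
    reconstruction the MMSE operator induces (with its hard-assignment
    counterpart), synthetic phantoms and MRC/STAR/CSV pose I/O, and a Monte
    Carlo benchmark harness for error-versus-noise, grid-resolution scaling,
    prior-mismatch and template-bias ("Einstein from Noise") studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
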