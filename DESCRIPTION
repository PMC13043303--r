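Package: depact
Title: Skull De-Aberration for Transcranial Photoacoustic Computed Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based correction of skull-induced aberrations in transcranial
    photoacoustic computed tomography (PACT). Implements a pseudo-spectral
    time-domain solver for the isotropic elastic wave equation (velocity-stress
    form, staggered grids, split-field perfectly matched layers), its exact
    discrete adjoint, and image reconstruction by universal backprojection,
    adjoint application, and accelerated proximal-gradient minimisation of a
    nonnegativity-constrained least-squares objective with L1 and isotropic
    total-variation regularisation. Includes rigid fiducial registration
    (Kabsch), skull mask extraction from CT/MR volumes, homogeneous elastic
    property assignment, synthetic vessel/skull-shell phantom generation, a
    model-perturbation study harness, and quantitative image evaluation
    (correlation, sliding correlation, SSIM, amplitude projections, line
    profiles).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    signal,
    yaml,
    jsonlite,
    EBImage,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
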