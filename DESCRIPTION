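Package: powderavg
Title: Orientationally-Averaged Diffusion MRI Signal Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimators of the orientationally-averaged ("powder-averaged")
    diffusion-weighted MRI signal from single-diffusion-encoding data:
    arithmetic and weighted shell averages, Lebedev spherical quadrature,
    spherical-harmonic and Cartesian-tensor isotropic components, optimal
    direction weights, and continuous averages from the spherical MAP-MRI
    (Mean Apparent Propagator) representation with positivity constraints or
    Laplacian regularization.  Includes gradient sampling-scheme generators
    (shelled, Lebedev, non-shelled, random, b-perturbed), a Watson-dispersed
    axisymmetric-tensor signal simulator with Gaussian and Rician noise, the
    closed-form ground-truth orientational average, and a Monte-Carlo
    evaluation harness with mean-absolute-error and b-correlated-bias
    metrics plus Anderson-Darling normality screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    nortest,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
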