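Package: rrtraj
Title: Random Regression Models for Genetic Trajectories over Repeated Harvests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits random regression mixed models to repeated harvest
    measurements from perennial-crop progeny trials. Random genetic, plot and
    permanent-environment effects are modelled as Legendre-polynomial
    functions of scaled harvest time with Kronecker-structured coefficient
    covariances; variance components are estimated by average-information
    REML with an EM fallback, and genetic values by BLUP from the mixed-model
    equations. Includes model selection by BIC and likelihood-ratio tests
    across polynomial orders and residual structures (homogeneous, diagonal,
    unstructured), post-processing into per-harvest heritabilities,
    selective accuracies, genetic correlations, eigenfunctions of the
    genetic covariance function, and area-under-trajectory rankings, and a
    synthetic half-sib randomized-complete-block trial generator with known
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
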