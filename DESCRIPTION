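Package: megcoreg
Title: Bayesian MEG Source Reconstruction Under Head-Position Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Source reconstruction for magnetoencephalography (MEG) that treats
    the co-registration between the cortical surface and the sensor array as an
    unknown. For a fixed head position, sources are estimated with a Multiple
    Sparse Priors (MSP) inversion whose hyperparameters maximise the variational
    free energy; the free energy then scores candidate head positions inside a
    Metropolis search over the six rigid-body degrees of freedom, with a
    Gelman-Rubin multi-chain stopping rule. Posterior head samples are combined
    by Bayesian model averaging to give posterior distributions over current
    density, head location, and the location of peak source activity. Includes
    an analytic single-sphere conductor forward model, a synthetic-data
    simulator (sinusoidal cortical patch sources with controlled sensor noise),
    eigenmode sensor-space reduction, and file-format plumbing for meshes,
    sensor layouts, fiducials and run configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
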