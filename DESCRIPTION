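Package: hippomeg
Title: Probabilistic Detection of Hippocampal Sources in MEG by Bayesian
    Model Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and empirical-Bayes source inversion framework for
    assessing whether magnetoencephalography (MEG) can detect hippocampal
    activity. Generates nested synthetic source spaces (a cortical
    hemisphere shell with a deep, curved hippocampal tube), computes
    spherical-conductor lead fields, simulates patch sources at controlled
    signal-to-noise ratios with optional co-registration error, inverts
    the sensor data under cortex-only and cortex-plus-hippocampus
    anatomical models with minimum-norm (MNE), empirical Bayes beamformer
    (EBB) and multiple-sparse-priors (MSP) covariance schemes, and decides
    between anatomical models via variational free-energy differences,
    random-effects Bayesian model selection and the Bayes omnibus risk.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
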