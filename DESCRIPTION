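Package: aedesmapr
Title: Bayesian Spatio-Temporal Modelling of Aedes Mosquito Trap Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hierarchical Bayesian count models for Aedes aegypti and Aedes
    albopictus vector-surveillance trap data: spike-and-slab predictor
    selection, Poisson / zero-inflated-Poisson / negative-binomial families
    compared by DIC, a Matern spatial random effect under penalized-complexity
    priors fitted by adaptive MCMC, posterior-predictive validation, kriging
    interpolation of the spatial field, and weekly gridded count prediction.
    Includes a synthetic trap-data generator for end-to-end testing and
    parameter-recovery studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
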