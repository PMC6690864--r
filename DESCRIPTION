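Package: bianus
Title: Bayesian Latent-Variable Modelling of Lifespan Performance Curves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Hierarchical Bayesian tools for modelling age-related growth and
    decline in longitudinal performance records, such as season-level athlete
    statistics. Provides four candidate age-change function families (power
    law, exponential, logistic, linear) with linearising transforms,
    per-individual broken-stick (Heaviside changepoint) estimation of the age
    of peak performance, a two-phase latent-variable model that links
    pre-peak development and post-peak aging factors through covariate
    loadings and an inter-factor correlation, deviance information criterion
    model comparison, and a synthetic-career simulator for parameter-recovery
    studies. Posterior sampling is performed with JAGS via 'rjags'.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    rjags,
    coda,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
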