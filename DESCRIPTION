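Package: rita
Title: Recurrent Individual Treatment Assignment for Longitudinal Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and evaluation toolkit for Recurrent Individual
    Treatment Assignment (RITA), a rank-based probabilistic policy that
    reassigns individuals between two competing interventions every period
    and thereby accommodates unobserved heterogeneous treatment effects.
    Provides generators for benchmark "worlds" with configurable latent and
    observed treatment-effect heterogeneity, the RITA policy with exploration
    bounds, RCT-derived baseline assignment policies, a common-random-number
    longitudinal simulation engine, and evaluation metrics (assignment
    proportions over time, average and individual cumulative outcome gains,
    subgroup medians by individually optimal arm).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ggplot2,
    grDevices,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
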