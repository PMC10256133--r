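Package: optinterim
Title: Simulation-Based Optimization of Interim Analysis Schemes for
    Event-Driven Survival Trials
Version: 0.1.0
Authors@R:
    person("Maintainer", "optinterim", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Plans and evaluates group-sequential monitoring schemes for
    event-driven two-arm survival trials. Constructs efficacy and nonbinding
    futility boundaries from power-family (Kim-DeMets) error-spending
    functions by recursive numerical integration, builds an assurance-style
    mixture prior on the log hazard ratio from historical-cohort summaries
    and the historical success rate of a development programme, simulates
    Weibull event-time trials under that prior, and searches a grid of
    candidate interim-analysis schemes for the design with the shortest
    expected duration, smallest expected sample size, or least drug
    exposure. Optimized boundary schemes can be applied retrospectively to
    observed per-look summaries (hazard ratios with confidence intervals)
    to reconstruct stop decisions and conditional power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
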