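Package: mscjs
Title: Bayesian Multistate Cormack-Jolly-Seber Models for Polar Bear
    Mark-Recapture and Telemetry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimation of survival, spatial state-transition, and recapture
    probabilities for the southern Beaufort Sea polar bear subpopulation from
    spring mark-recapture and satellite-telemetry data, using Bayesian
    multistate Cormack-Jolly-Seber models with a marginalized hidden-Markov
    likelihood.  Includes the spatial-state study design utilities (state
    assignment, search-track filtering, effort compilation), encounter-history
    data management and summaries, a synthetic-data generator that emulates
    the study design, an adaptive Metropolis-within-Gibbs sampler, derived
    Horvitz-Thompson abundance with an alive-proportion expansion,
    convergence/model-comparison/goodness-of-fit assessment, and an
    individual-based population projection used as a consistency check
    between survival and abundance estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    coda,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
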