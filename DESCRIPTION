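Package: ratchetphy
Title: Comparative Phylogenetics of Irreversible Niche Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying repeated, irreversible ("ratchet-like") evolution
    of a discrete ecological niche on time-calibrated phylogenies, developed around
    the case of diving in waterbirds. Provides constrained continuous-time Markov
    (Mk) models of discrete niche evolution with no-reversion rate patterns,
    stochastic character mapping with transition counting and node posteriors,
    the DR tip speciation-rate statistic, simulation-based phylogenetic ANOVA
    with Holm-corrected pairwise tests, state-dependent diversification models
    (BiSSE and hidden-state extensions), multi-regime Brownian-motion and
    Ornstein-Uhlenbeck models of continuous trait evolution on painted trees,
    AIC-weight model selection, and synthetic-data generators emulating a
    727-species waterbird dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    phytools,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
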