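Package: mcepisodes
Title: Episode Counts and Lengths for Absorbing Markov Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for discrete-time absorbing Markov chains used in health
    expectancy research: fundamental-matrix occupancy times, expected numbers
    and average lengths of episodes in a state (or set of states) computed
    analytically with Markov chains with rewards, conversion of
    occurrence-exposure transition rates into transition probabilities,
    maximum-likelihood estimation of transition probabilities from
    longitudinal panel data, and sampling-variance estimation by block and
    model-based (multinomial) bootstrap with percentile confidence intervals.
    Includes a Monte-Carlo simulation module that serves as an independent
    oracle for the analytical results and generates synthetic panels, with
    and without between-individual heterogeneity, for estimator validation
    and bootstrap bias studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    mstate,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
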