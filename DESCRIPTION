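Package: gridrt
Title: Lattice Diffusion Models of Response Times with Entropic Barriers
Version: 0.1.0
Authors@R:
    person("gridrt", "developers", email = "gridrt@example.org",
           role = c("aut", "cre"))
Description: Simulates first-passage times of random walks on
    two-dimensional lattices, either obstructed by randomly scattered
    reflecting nodes (entropic barriers) or biased outward by an
    acceptance-cost rule (a grid drift-diffusion model), and fits both
    models to response-time distributions by Jensen-Shannon-divergence
    minimization.  Includes exact absorbing-Markov-chain and closed-form
    one-dimensional first-passage references used to validate the
    simulators, cross-validated model comparison, population analyses
    (per-instant fits, per-player fits, similarity rankings, and
    rating-quintile parameter correlations), and a seeded generator of
    synthetic response-time corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
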