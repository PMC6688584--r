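Package: commitval
Title: Commitment-Based Motion Models and Pass Decision Valuation for
    Player Tracking Data
Version: 0.1.0
Authors@R:
    person("commitval", "developers", email = "dev@commitval.invalid",
           role = c("aut", "cre"))
Description: Fits probabilistic player motion models ("commitment models")
    from spatiotemporal tracking and match-event streams by two-class
    four-dimensional kernel density estimation, aggregates them into team
    influence, spatial dominance and pass-outcome probabilities, and scores
    every passing option by risk (dominance x influence) and reward (field
    equity) to produce expected-outcome and decision-value metrics for each
    executed pass relative to the best available alternative. Includes a
    seeded synthetic match generator with known ground-truth commitment
    behaviour so the full pipeline is testable without proprietary tracking
    data, plus rank-based statistical comparison utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
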