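Package: phyloallometry
Title: Phylogenetic Allometry, Prediction Intervals and Stereological
    Estimation for Comparative Neuroanatomy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for asking whether a focal species' brain structure is
    exceptionally large for its body of comparison. Fits log-log allometric
    regressions by phylogenetic generalized least squares with
    maximum-likelihood Pagel's lambda, draws phylogeny-aware 95% prediction
    bands and flags outlier species, runs a Bayesian posterior-predictive
    test for a left-out focal species over a set of candidate trees, and
    implements the measurement-side estimators (optical-fractionator cell
    counts with Gundersen-Jensen coefficients of error, Cavalieri
    serial-section volumes) together with two-species summary comparisons.
    A seeded synthetic-data generator produces birth-death trees, traits
    evolving under attenuated Brownian motion, two-species specimen tables
    and sectioned 3-D cell fields so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nlme,
    jsonlite,
    optparse
Config/testthat/edition: 3
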