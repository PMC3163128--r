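Package: nmfdl
Title: Vague-to-Crisp Mixture Estimation with Neural Modeling Fields and
    Dynamic Logic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic-annealing, vague-to-crisp mixture-model
    estimation ("dynamic logic") with data-driven model activation and a
    skeptic complexity penalty.  A generic fitting engine is parameterized
    by pluggable model families: Gaussian clusters, travelling phase-cone
    events on sensor arrays with a background clutter component, Bernoulli
    models that learn "situations" (characteristic object subsets) from
    binary co-occurrence data, and a paired language-cognition (dual)
    Bernoulli family in which both channels share one association
    variable.  Includes seeded synthetic-data generators for all three
    applications, recovery diagnostics, plain-text file round-tripping and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
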