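Package: adaptlv
Title: Evolutionary Lotka-Volterra Dynamics of Adaptive Abiraterone
    Therapy in Prostate Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the evolutionary game between three prostate cancer
    phenotypes (androgen-dependent T+, testosterone-producing TP, and
    androgen-independent T-) under abiraterone therapy, using Lotka-Volterra
    competition equations with drug- and state-dependent carrying capacities
    and a serum PSA proxy. Enumerates the admissible competition matrices
    implied by the model's partial order on competition coefficients, computes
    untreated equilibrium communities and invasion fitness, classifies virtual
    patients into responder categories, and compares four treatment policies
    (untreated, continuous maximum tolerated dose, metronomic cycling, and
    adaptive 50 percent-PSA cycling) by time to competitive release of the
    resistant clone and cumulative drug dose. Also reproduces the exact
    contingency statistics and cumulative-dose summaries of the associated
    pilot trial cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
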