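Package: frlearn
Title: Learning-Modulated Predator Functional Responses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates predator functional responses in which the attack
    rate and the handling time improve with foraging experience through
    exponential learning curves. Couples the learning curves into Holling
    (constant prey density) and Rogers (prey depletion) consumption
    dynamics solved by fixed-step fourth-order Runge-Kutta integration,
    classifies the emergent response shape (type I, II, III and the
    near-type intermediates) from finite-difference second derivatives,
    and maps shape regions over learning-parameter space with a fast
    compiled sweep engine. Includes closed-form and root-finding oracles
    (Holling disk equation, Rogers random-predator equation) used to
    validate the integrator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
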