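Package: rgbgame
Title: Stochastic Reference-Gamble-Birth Dynamics and Extinction Scaling
    in Cyclic Competition
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Agent-based Monte Carlo simulation of the rock-paper-scissors
    (cyclic competition) game on finite, structured populations using the
    local three-party Reference-Gamble-Birth (RGB) update, together with
    the analysis stack needed to study extinction dynamics: the replicator
    equation limit and its linear stability, finite-size scaling collapse
    of mean extinction times with critical exponents, mapping of a local
    gain on a structured network to a global gain on the fully-connected
    reference by matching the exponential characteristic constant, and
    spatial/temporal correlation estimation with exponential and
    damped-cosine fits on the two-dimensional periodic grid.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
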