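Package: coopfix
Title: Fixation of Cooperation on Networks with Personalised Update Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Evolutionary dynamics of the donation game on arbitrary
    undirected networks in which every node revises its strategy at its own
    Poisson rate. Provides exact computation of the critical benefit-to-cost
    ratio from coalescing random-walk meeting times, a fast mean-field
    approximation and its large-network asymptotics, an event-driven
    Monte-Carlo engine for fixation probabilities and long-term payoffs, an
    exact finite-state Markov-chain oracle for small populations, and a
    gradient-descent optimiser (RMSProp with implicit differentiation of the
    coalescence system) that tunes per-node update rates to minimise the
    cooperation threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
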