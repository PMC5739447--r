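Package: cdlogic
Title: Logic-Based Dynamic Analysis of Central Dogma Boolean Models
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Boolean network machinery for the logical models of the central
    dogma of molecular biology: a rule grammar and parser, synchronous and
    asynchronous update semantics, exhaustive state-transition-graph
    construction with attractor and basin-of-attraction analysis, exact
    Markov-chain iteration for probabilistic Boolean networks, centrality
    and in-degree inequality (Gini) statistics of state-transition graphs,
    and perturbation-robustness measurement (normalized Hamming distance)
    with significance testing against randomized-network null ensembles.
    Ships a curated catalog of 4-node (1965) and 7-node (present-day)
    central dogma models, a random Boolean network generator, and readers
    and writers for BoolNet-style text and SBML-qual files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
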