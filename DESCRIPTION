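Package: cartlogic
Title: Stochastic Logic-Based Simulation of CAR T-Cell / Tumor Cell Signaling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for probabilistic Boolean (stochastic discrete logic)
    models of intracellular signaling, built around a curated 59-node model of
    chimeric antigen receptor (CAR) T-cell activation, cytokine, cytotoxic and
    inhibitory signaling during engagement of tumor cells. Nodes carry logical
    update rules gated by activation and degradation propensities and are
    updated in a freshly randomized order each iteration; ensembles of
    replicates yield per-node activity trajectories and steady-state signature
    fractions. Includes a plain-text model format with parser and validator,
    dependency-graph extraction with edge signs, an exact Markov-chain
    transition kernel for small models (a simulation oracle), named
    receptor-ligation scenarios, a knockout/overexpression perturbation scan,
    and a command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
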