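Package: firetree
Title: Tree-Cover Dynamics Under Stochastic Switching Between Fire and
    No-Fire Regimes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates stage-structured tree-cover dynamics in moist savannas
    and tropical forests as a Markov jump linear system: two Lefkovitch
    projection matrices (one for fire years, one for fire-free years) are
    selected each year by a Bernoulli fire draw whose probability is a
    decreasing function of tree cover, closing a fire-vegetation feedback.
    Provides closed-form steady states and norm-based stability checks,
    an Ulam-type discretization of the state space into a finite Markov
    chain with its stationary distribution, permanence ratios, an empirical
    two-state fire chain, a histogram-based bimodality index, parameter
    sensitivity grids, and seeded multi-site ensembles that mimic spatial
    sampling of tree cover.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
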