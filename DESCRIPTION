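Package: fluxdecomp
Title: Functional Decomposition of Metabolic Fluxes and Proteome Allocation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes optimal steady-state flux solutions of genome-scale
    metabolic models into mass-balanced, function-specific flux components
    (one per demand flux: biomass building blocks, maintenance ATP, constrained
    byproduct excretion), using finite-difference response coefficients around
    a two-stage parsimonious FBA solution. Provides flux coupling into
    respiration and fermentation modes, per-reaction functional shares with a
    mixed (cancellation) fraction, hierarchical functional-module detection,
    carbon and ATP cost accounting for biosynthesis, projection of functional
    shares onto proteins through gene-protein-reaction rules, greedy GO-term
    proteome categorization, and a five-sector coarse-grained proteome
    allocation model that predicts the respiration/fermentation switch and
    acetate overflow. Includes deterministic toy-network fixtures with
    analytically known decompositions and synthetic data generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    quadprog,
    jsonlite,
    xml2,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
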