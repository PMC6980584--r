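Package: twocellfba
Title: Two-Cell Regulated Flux Balance Analysis for Heterocystous Cyanobacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based modelling toolkit for filamentous, heterocyst-forming
    cyanobacteria. Reads and writes stoichiometric models (SBML Level 3 FBC and a
    strict tabular dialect), assembles biomass objective functions from
    macromolecular compositions, and solves flux balance analysis (FBA), flux
    variability analysis (FVA), L1-minimal flux distributions and 2-D robustness
    scans with an internal bounded-variable simplex that exposes dual values.
    Composes two-cell (vegetative + heterocyst) models with intercellular
    sucrose/glutamate/glutamine shuttles, a shared photon budget and biomass
    coupling; integrates cell-type gene expression through per-gene flux-capacity
    constraints on an irreversible, OR-free expansion of the network
    (transcription-regulated FBA) with gene-level shadow prices; and runs
    hydrogen-production analyses (H2 x O2 robustness surfaces, maximal/minimal H2
    at suboptimal growth, differential flux reports, bidirectional-hydrogenase
    contribution). Ships a deterministic photoautotrophic/diazotrophic toy network
    so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
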