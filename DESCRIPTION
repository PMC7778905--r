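Package: xrefforge
Title: Reconciliation of Metabolite and Reaction Namespaces for
    Genome-Scale Metabolic Models
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a unified namespace for metabolites and biochemical
    reactions from multiple source databases, using molecular-structure
    evidence (InChI layer normalization) and reaction-context evidence,
    with automated conflict detection and deterministic identifier
    assignment.  Maps genome-scale metabolic networks (SBML level 2 or
    level 3 with FBC) onto the unified namespace with per-entity
    diagnostics, and classifies every reaction's flux-carrying status
    (A/a/b/B) under three bound-relaxation regimes with a flux
    variability variant, so that reconciliation can be verified to
    preserve model properties.  Includes a synthetic fixture generator
    with known ground truth, exact rational-arithmetic oracles
    (nullspace rank tests and flux-polytope vertex enumeration), and
    TAB-delimited distribution file readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
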