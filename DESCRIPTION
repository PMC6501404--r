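Package: gsmmr
Title: Constraint-Based Analysis of Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constraint-based modeling of bacterial metabolism:
    a tabular model dialect with reader/writer, flux balance analysis (FBA)
    and flux variability analysis (FVA) on a built-in bounded-variable
    simplex, gene-protein-reaction (GPR) boolean logic, in silico
    single-gene-deletion essentiality scans with subsystem vulnerability
    summaries, and integration of RNA-seq expression levels (RPKM) into
    flux constraints via geometric-grid discretization with either
    bound-clamping or an iMAT-style mixed-integer agreement maximization.
    Includes a synthetic-data generator producing toy central-metabolism
    networks and random models with planted essential genes, plus
    log-normal expression tables, so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    boot,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
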