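Package: selscreen
Title: Ligand-Based Virtual Screening with Multitask Threshold QSAR and
    Target-Selectivity Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A ligand-based virtual screening pipeline for discovering
    receptor-subtype-selective antagonists, modelled on dopamine receptor
    pharmacology (D4 as the target, D2/D3/D5 as anti-targets). Converts
    confirmatory potency measurements (IC50/Ki/Kd with censoring) into
    multi-threshold activity labels, trains one multitask probabilistic
    classifier per receptor over hashed circular substructure fingerprints,
    composes per-receptor threshold probabilities into activity and
    selectivity scores, and runs a two-stage screening funnel with
    enrichment evaluation. Includes a synthetic chemistry benchmark
    generator (fragment-grammar molecule assembly, latent structure-activity
    map with cross-receptor correlation, simulated confirmatory assays) so
    the whole funnel is testable against known ground truth, plus standard
    receptor pharmacology calculators (one-site percent inhibition,
    Cheng-Prusoff conversion).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    Matrix,
    igraph,
    jsonlite,
    pROC,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
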