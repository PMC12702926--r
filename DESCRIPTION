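Package: hybscreen
Title: Fragment Hybridization and Deep-Learning Virtual Screening for
    Allosteric Kinase Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for ligand-based discovery of allosteric kinase
    inhibitors built around four stages: BREED-style three-dimensional
    fragment hybridization of binding-site-aligned ligands (fragmentation at
    acyclic single bonds, bond-vector matching under displacement and angle
    tolerances, recombination and sanitization), an ECFP4 multilayer
    perceptron bioactivity classifier with a full classification metric
    panel, applicability-domain / drug-likeness / synthetic-accessibility
    triage of screening libraries, and early-recognition enrichment
    statistics (ROC-AUC, RIE, BEDROC, enrichment factors) together with
    MM/GBSA energy-decomposition aggregation and docking-selectivity
    reporting. Ships deterministic synthetic-data generators so every stage
    is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    methods
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: OpenBabel (the 'obabel' command-line tool)
Config/testthat/edition: 3
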