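Package: orthoGEM
Title: Orthology-Guided Projection and Validation of Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Projects a curated genome-scale metabolic model from a scaffold
    species onto a target species. Gene-protein-reaction (GPR) boolean rules are
    rewritten through a consensus ortholog map built by voting over several
    ortholog-detection methods, conserved reactions are carried over together
    with compartments and non-enzymatic transports, species-specific reactions
    can be inserted, and the biomass DNA precursors are re-balanced for the
    target genome's GC content. The projected draft is checked for network gaps
    (dead-end metabolites, blocked reactions) and validated by flux balance
    analysis against tables of growth/no-growth experiments, summarised as a
    confusion matrix with geometric-mean accuracy. Includes SBML Level 2
    Version 4 (COBRA notes dialect) read/write and a deterministic generator of
    synthetic scaffolds, ortholog maps with planted evolutionary events, and
    experiment tables.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
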