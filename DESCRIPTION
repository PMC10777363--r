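Package: pgxvis
Title: Graph-Based Visualization of Pharmacogenomic Plausibility-Check Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joins a drug-metabolism pathway (PharmGKB-style tab-separated
    tables) with a patient's pharmacogenomic check report (gene-variant calls
    and per-drug dosing guidelines from a clinical decision support system)
    into an annotated network graph. Enzyme nodes are duplicated per reaction
    and carry metabolizer-status symbols (poor, intermediate, normal,
    ultrarapid); dosing guidelines are attached to the enzymes that they
    concern, and contradictory recommendation categories for the same drug are
    detected and flagged. Provides a deterministic force-directed layout, a
    self-contained interactive HTML report, static SVG rendering, GraphML and
    node-link JSON export, a seeded synthetic case generator, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    xml2,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
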