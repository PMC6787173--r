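Package: phagoscreen
Title: Simulation and Statistics for High-Content miRNA Phagocytosis Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to simulate, gate and analyse flow-cytometry based
    high-content screens for regulators of macrophage phagocytosis. Generates
    event-level synthetic data for 96-well plates (scatter, viability,
    transfection and bead-uptake channels) with known ground truth, reduces
    events to per-well readouts through a hierarchical gating scheme, and calls
    hits with on-plate non-targeting normalization, per-plate one-way ANOVA
    with Dunnett many-to-one adjustment, dual fold-change/significance cut-offs
    and two-stage intersection. Also implements the companion validation-arm
    statistics: repeated-measures ANOVA with Greenhouse-Geisser correction,
    2^(-dCT) qPCR quantification, dual-luciferase normalization, colony-count
    titre estimation, and a canonical miRNA seed-site scanner with binding-site
    mutagenesis for reporter constructs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    yaml
Config/testthat/edition: 3
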