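Package: cycloscan
Title: Structural Comparison and S2-Pocket Specificity Screening of
    Cyclophilin PPIase Domains
Version: 0.1.0
Authors@R:
    person("Core", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for family-wide structural comparison of peptidyl-prolyl
    isomerase (cyclophilin) domains and for in silico substrate-specificity
    screening of their S2 pocket.  Reads PDB/mmCIF coordinate files, performs
    Kabsch superposition and structure-guided residue mapping onto the PPIA
    reference numbering, quantifies the S2-pocket "gatekeeper" geometry and
    classifies isoform surfaces, and runs a tethered Monte-Carlo docking
    screen of all 400 X-Z-Gly-Pro tetrapeptides with flexible P2/P3 and
    gatekeeper sidechains, scored by a documented binding-energy estimate
    plus an S2-penetration distance metric.  Results are summarised as
    20x20 P3xP2 specificity arrays.  A synthetic-receptor generator with
    known ground truth makes every stage testable without downloading
    structures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
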