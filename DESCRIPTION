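Package: pepbridge
Title: Peptide Mass Reconciliation and Disulfide Connectivity from NMR
    Restraint Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for characterizing disulfide-rich peptides from mass
    spectrometry and NMR evidence: exact monoisotopic mass and isotope
    pattern arithmetic with post-translational modifications (methionine
    sulfoxide, C-terminal amidation, carbamidomethyl cysteine, disulfide
    bridges), b/y fragment ions and isoelectric points; exhaustive
    explanation of measured-versus-calculated mass differences by
    modification multisets and C-terminal extensions; NOE distance-class
    restraints and Karplus coupling interpretation; coarse-grained ensemble
    generation by distance-geometry embedding and seeded simulated
    annealing; and disulfide connectivity calling by scoring all perfect
    matchings of cysteines against ensemble-averaged sulfur distances.
    Includes seeded synthetic-data generators so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
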