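Package: episce
Title: Subcellular-Element Simulation of Epithelial Cross-Section Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An energy-based subcellular element (SCE) model of a 2D
    epithelial cross-section patterned after the Drosophila wing imaginal
    disc: overdamped node dynamics driven by membrane, adhesion,
    contractile, bending, Morse volume-exclusion and area-constraint
    potentials; cell growth, mitotic rounding with interkinetic nuclear
    migration, centerline-based cell division, and tension-triggered ECM
    remodeling.  Includes spatial parameter patterning along the
    anterior-posterior axis, scenario presets, and tissue-shape metrics
    (local basal curvature, cell height, relative nuclear position) for
    calibration against experimental cross-sections.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
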