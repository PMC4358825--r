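Package: fluorcell
Title: Quantitative Fluorine-19 MRI Cell Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and quantification tools for fluorine-19 MRI cell
    tracking with perfluorocarbon-labeled cells. Generates synthetic 3D
    magnitude-image phantoms with exact ground truth (cell pellets, an
    external reference tube of known 19F spin concentration, and an
    off-resonance compartment modelling the isoflurane artifact), calibrates
    the per-cell 19F spin loading from comparative NMR spectra, converts ROI
    image signal to absolute cell counts by reference normalization, and
    analyzes longitudinal cell-count decay with repeated-measures ANOVA
    using Greenhouse-Geisser sphericity correction and Tukey post-hoc tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
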