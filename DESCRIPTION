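Package: molbool
Title: Simulation and Quantification of Boolean Proximity Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dual-recognition rolling-circle proximity assays that
    report both free proteins and protein complexes (NOT / AND readout).
    Provides a sequence-level model of the assay DNA logic (circle assembly,
    arm hybridization, nicking-endonuclease site selection, reporter-tag
    incorporation, padlock circularization and rolling-circle
    amplification), a stochastic simulator that turns ground-truth protein
    populations into multi-channel fluorescence images with per-molecule
    truth tables, a spot-calling and dual-channel classification pipeline
    (nucleus segmentation, cell delineation, top-hat speckle enhancement,
    angled intensity thresholds, per-cell summaries), and the nonparametric
    statistics used to compare per-cell quantities between conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
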