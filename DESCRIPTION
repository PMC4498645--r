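Package: lasercnv
Title: Quantification and Quality Control of Laser-Induced Choroidal
    Neovascularization Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end analysis pipeline for the mouse laser-induced
    choroidal neovascularization (CNV) model: constant-threshold
    segmentation of IB4-stained lesions on RPE/choroid/sclera flat-mounts
    with calibrated area measurement, hemorrhage grading by the ratio of
    bleed major axis to lesion diameter, rule-based lesion and eye
    exclusion (Bruch's membrane rupture failure, choroidal damage, fused
    lesions, 5x-mean outliers, sole survivors), fundus fluorescein
    angiography leakage scoring from 5- and 10-minute image pairs, and
    group summary statistics with relative-area reporting. A seeded
    synthetic-eye generator emits images plus ground-truth metadata with
    realistic lesion geometry, area distributions and complication
    frequencies, so every stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
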