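Package: sonocyst
Title: Cystic Region Estimation and Observer Variability Analysis for
    Thyroid Nodule Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-support analysis for estimating the cystic (fluid)
    fraction of thyroid nodules on B-mode ultrasound. Provides a seeded
    speckle-phantom generator with known solid/cystic composition and
    simulated annotators; binary-mask arithmetic including multi-annotator
    ground-truth averaging; a hand-crafted texture feature core that scans
    20x20 patches into four directional signals, splits each into three
    frequency bands and summarises every band by an order-2 autoregressive
    fit (36 features per patch); a random-forest patch classifier aggregated
    into nodule-level cystic percentages; and inter-observer statistics
    (variance percentage with its NA convention, composition-category match
    percentages and a chi-squared test), together with machine-readable
    transcriptions of the published comparison tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    tiff,
    randomForest,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
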