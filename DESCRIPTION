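Package: thyrocascade
Title: Cascade Frequency-Domain and CNN Classification of Thyroid Ultrasound Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computer-aided classification of thyroid-nodule ultrasound frames
    into benign and malign cases by a two-stage cascade. A preprocessing stage
    extracts the thyroid tissue region by Otsu binarization, 8-connected
    labeling and largest-object selection; a frequency-domain stage scores the
    2-D power spectrum of the tissue crop against parametric spectral masks
    (circle, horizontal, vertical, plus, circle-plus) and pre-classifies each
    frame as benign, malign, or undecided using two calibrated thresholds; a
    small convolutional network with a global-average-pooling head resolves the
    undecided band. Includes a synthetic ultrasound-phantom generator with
    ground truth, patient-level cross-validation, and sensitivity/specificity
    reporting, so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    stats,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
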