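Package: nephroseg
Title: Segmentation-Based Quantification of Acute Kidney
    Ischaemia-Reperfusion Injury in Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Whole-section quantification of acute ischaemia-reperfusion
    injury (IRI) in PAS-stained mouse kidney histology. Provides an
    encoder-only convolutional segmentation network emitting an
    8x-downsampled multiclass label mask, pixel-percentage injury scoring,
    grid heatmaps of pathological classes, pixel-wise evaluation
    (confusion matrix, precision/recall/specificity/F1), a semi-quantitative
    field-of-view scorer for comparison, and a synthetic pseudo-PAS kidney
    section generator with paired ground-truth masks so the full pipeline is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
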