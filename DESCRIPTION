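Package: pewidth
Title: Automated Pericardial Effusion Width Measurement from Echocardiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for automated measurement of pericardial
    effusion (PE) width from echocardiography clips. Implements moving-window
    view selection (a 48-frame sliding-window view/quality filter over
    per-frame view-classification scores), a pluggable per-frame segmentation
    contract with a reference intensity-band segmenter, a geometric maximal
    width calculator that measures boundary-normal chords through the
    segmented PE mask, clinical severity grading (small/moderate/large), the
    agreement and classification metrics used to evaluate such pipelines
    (Dice, MAE, ICC, R-squared, ROC AUC, sensitivity/specificity), synthetic
    phantom and video generators with analytically known widths, and minimal
    multi-frame DICOM input/output with pixel-spacing calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    pROC,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
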