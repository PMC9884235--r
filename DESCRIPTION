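Package: choroidqc
Title: Choroid-Region Diagnostic Quality Assessment of OCT B-Scans with
    Explainable Attention Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the diagnostic quality of the choroid
    region in optical coherence tomography (OCT) B-scans. Provides a
    synthetic layered-tissue B-scan simulator with exact ground-truth
    choroid masks; a binary good/bad quality classifier (compact
    convolutional network trained from scratch) evaluated under
    stratified K-fold cross-validation with accuracy, precision, recall,
    F1 and AUC at the maximum-accuracy operating point; Grad-CAM saliency
    maps; color transparency map (CTM) renderings in which per-pixel
    relevance attenuates the grayscale image and irrelevance fills a red
    mask; the choroid-coverage explainability scores OCC (overall choroid
    coverage) and CCVR (choroid coverage within the visible region); and
    inter-rater agreement scoring. A pipeline driver orchestrates all
    stages from a single configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    pROC,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
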