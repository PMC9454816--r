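Package: karyoscan
Title: Automated DNA Karyometry for Cytologic Cancer-Cell Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A complete, testable pipeline for diagnostic DNA karyometry of
    Feulgen-stained cytologic preparations: simulation of focal-stack slide
    images with full ground truth, extended depth-of-focus fusion and
    background-corrected densitometry, nuclear segmentation and an
    18-feature morphometric description, random-forest classification of
    nuclei into eight diagnostic classes with a gallery-correction and
    retraining workflow, internal DNA calibration by iterative outlier
    trimming, ESACP-style stemline and single-cell aneuploidy detection,
    DNA malignancy grading, specimen-level diagnosis, and diagnostic
    accuracy evaluation against a follow-up reference standard.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    ranger,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
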