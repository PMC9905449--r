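Package: qspect
Title: Local Radiomic Analysis of Perfusion SPECT/CT for Pulmonary
    Embolism and Pneumonia Pattern Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for the local (pixel-wise) radiomic analysis of paired
    perfusion SPECT and CT volumes. Registers and normalizes the two
    modalities, extracts a reproducibility-selected set of 2D first-order and
    texture features (GLCM, GLDM, GLRLM) from small windows centered at every
    annotated region-of-interest pixel, classifies each window sample into six
    tissue-pattern classes with a class-weighted fully connected network, and
    aggregates sample predictions into lesion-level diagnoses of pulmonary
    embolism, pneumonia and healthy lung. Includes leave-one-patient-out
    evaluation, ROC comparison against a gold-standard model, and a synthetic
    phantom cohort generator for end-to-end testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    pROC,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
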