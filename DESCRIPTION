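Package: dfmorph
Title: Displacement-Field Morphometry for Alzheimer's Detection on Brain MR Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for detecting Alzheimer's disease from structural brain
    MR images using per-pixel displacement fields. Coronal key slices are
    ranked by inter-class variance; a level-set motion scheme estimates the
    non-rigid displacement field between a normal template and each subject;
    polar-encoded fields are reduced by principal component analysis and
    classified with a linear support vector machine, a generalized eigenvalue
    proximal SVM (GEPSVM) or a twin SVM (TSVM); displacement magnitudes above
    a threshold flag disease-related regions. Includes a synthetic coronal
    brain-phantom generator with known ground-truth deformations and repeated
    stratified cross-validated evaluation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    kernlab,
    jsonlite,
    RNifti,
    withr
Suggests:
    testthat (>= 3.0.0),
    e1071,
    yaml,
    optparse
Config/testthat/edition: 3
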