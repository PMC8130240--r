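Package: ctdosemap
Title: Deformable CT Registration and Dose Accumulation for Combined
    External-Beam and Brachytherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping absorbed dose between the external-beam and
    brachytherapy planning frames of combined cervical-cancer radiotherapy.
    Implements a weighted-window Lucas-Kanade optical-flow solver wrapped in
    a coarse-to-fine image pyramid for deformable CT-to-CT registration,
    applicator in-painting, affine preregistration, EQD2 conversion under the
    linear-quadratic model, deformation-based dose accumulation, and an
    evaluation suite (landmark distance, HU RMSE, 2D gamma analysis, DVH
    hot-spot parameters). Includes a minimal DICOM reader/writer for CT
    series, RTDOSE and RTSTRUCT objects, and a deterministic pelvic phantom
    generator with ground-truth deformation fields for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
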