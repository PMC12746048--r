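Package: transitgamma
Title: Transit Dosimetry Gamma Analysis and Failure-Mode ROC Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating the error-detection performance of EPID
    transit dosimetry. Provides a 2D gamma-index engine (dose-difference /
    distance-to-agreement, global or local normalization, low-dose
    threshold), a synthetic generator of paired base/erroneous transit dose
    images covering five radiotherapy failure modes (linac hardware and
    output errors including a fully retracted MLC, breathing-phase
    mismatches, patient swaps, wrong planning CT, missing bolus),
    SEAFARER-style error injection into minimal DICOM RT Plan structures,
    and ROC analysis (AUC, Youden-J optimal passing-rate cutoff) that
    identifies the gamma criterion and tolerance maximizing sensitivity and
    specificity for dose deviations above a chosen magnitude. Reads and
    writes single-plane DICOM RT Dose and a plain-text grid format.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
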