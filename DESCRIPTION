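Package: localaim
Title: Neural Prediction of Atomic and Interatomic Real-Space Chemical Descriptors
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts locally defined (one-body atomic and two-body
    interatomic) real-space chemical descriptors -- QTAIM atomic charges,
    localization and delocalization indices, and IQA intra-atomic and
    interatomic energy components -- from molecular geometries with a
    continuous-filter convolutional neural network whose pooling layer is
    removed so that per-particle outputs are retained. Includes universal
    and particle-type-specific readout heads, electron-count sum-rule
    bookkeeping with a reconstruction-based uncertainty score, a
    physically consistent surrogate-label generator for benchmarking, and
    group-delocalization trajectory analysis for detecting supramolecular
    binding events.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
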