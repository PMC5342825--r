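Package: flashresp
Title: Flash-Response Calcium Imaging Analysis and Genetic Disruption
    Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for two-photon calcium imaging of visually
    evoked responses in Drosophila, together with the statistics used in
    conditional gene-disruption screens. Covers photobleaching correction
    by double-exponential fitting, deltaF/F computation, stimulus-locked
    resampled averaging with moving-window smoothing, responder
    classification and peak-response statistics; 3D spot colocalization
    counting of reporter-labelled cells; Mendelian survival expectation
    with one-proportion z-tests and Fisher's exact tests; delta-delta-Ct
    relative transcript quantification; and a seeded synthetic-data
    generator that produces imaging movies, ROI traces, spot clouds, Ct
    tables and cross counts with known ground truth for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
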