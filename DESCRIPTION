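Package: cspkblink
Title: Eyeblink Conditioning and Purkinje Cell Complex-Spike Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A desk-scale analysis pipeline for delay eyeblink conditioning
    experiments in head-fixed mice: eyelid videometry (thresholding and
    moment-based ellipse fitting of eye videos), conditioned-response
    detection and session-level learning metrics, extracellular Purkinje
    cell spike-train analysis (simple-spike/complex-spike detection,
    spikelet counting, peri-stimulus histograms, evoked complex-spike
    probability and latency), classical two-tailed Student's t-test group
    comparisons, and optical-fiber irradiance prediction for optogenetic
    stimulation. A synthetic-session generator emulates trial structure,
    eyelid kinematics, eye videos and 25-kHz voltage traces with stored
    ground truth, so the whole pipeline is testable without animal data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    yaml,
    tiff,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
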