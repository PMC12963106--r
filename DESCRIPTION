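Package: iohpredict
Title: Early Intraoperative Hypotension Prediction from Arterial Pressure Waveforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for early prediction of intraoperative
    hypotension (IOH) from continuous arterial blood pressure (ABP) waveforms.
    Provides a synthetic ABP generator with ground-truth annotations, beat
    detection and signal-quality control, hypotension event detection with
    burden metrics (AUT, TWA), Poisson-process sliding-window data-point
    framing and labeling with observation/prediction/slack windows, a
    MAP-threshold baseline classifier and a 7-layer 1-D convolutional neural
    network, and a patient-grouped cross-validation and cross-cohort
    evaluation framework including class-separation (delta-mean)
    standardization by binned stratified resampling.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
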