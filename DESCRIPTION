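Package: fidnavQC
Title: Motion Monitoring and Diagnostic-Quality Prediction from FID Navigators
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for detecting head motion in structural MRI from free
    induction decay (FID) navigator signals recorded by a multi-channel
    receive coil array. Implements four per-repetition coil-combination
    motion metrics, k-space partition-weighted integration into per-scan
    motion scores, ROC threshold selection with Youden's index and the
    0.632 bootstrap, agreement and correlation statistics against
    radiologist image grades, and a scan-abort model that quantifies the
    time and cost saved by terminating motion-corrupted acquisitions. A
    digital-phantom forward simulator generates multi-coil navigator
    series with known rigid-motion ground truth so the whole pipeline can
    be exercised without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), pROC, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
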