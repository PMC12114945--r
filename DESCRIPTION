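Package: emgonset
Title: Onset Detection for Slowly Activated Muscle from Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the onset of muscle activation in single-channel surface
    electromyography (sEMG), with emphasis on slowly activated muscles such as
    the soleus whose gradual amplitude and spectral transitions defeat fixed
    amplitude thresholds. The core detector tracks the normalized Shannon
    entropy of the Hilbert marginal spectrum (obtained by empirical mode
    decomposition and the Hilbert transform) over sliding windows and places
    the onset at the steepest drop of the smoothed entropy trend. Comparison
    detectors (relative amplitude threshold, Teager-Kaiser energy, RMS
    windowing, wavelet energy redistribution), ablation variants, a seeded
    generator of surrogate slow-activation sEMG with known ground truth, and
    an evaluation harness (sensitivity, specificity, FNR, FPR, onset RMSE,
    detection advance) are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
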