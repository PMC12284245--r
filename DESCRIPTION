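Package: thetasource
Title: Hippocampal Theta Power and Cortico-Hippocampal Connectivity from
    Scalp EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: End-to-end pipeline for estimating hippocampal theta-band
    activity and cortico-hippocampal phase connectivity from multichannel
    scalp EEG.  Provides a synthetic-data generator (spherical head
    models, analytic dipole leadfields, theta-burst source activity,
    1/f background noise, blink artifacts, and crossover study tables),
    preprocessing (resampling, zero-phase Hamming-window FIR filtering,
    correlation-based bad-channel detection, ICA-based ocular artifact
    rejection), theta-burst detection with Morlet wavelets and
    phase-realigned epoching, hierarchical subspace-pursuit sparse
    source localization with SVD-reduced patch leadfields and a
    mutual-coherence constraint (including subcortical sources),
    weighted phase-lag index connectivity, and Bayesian random-intercept
    linear mixed models for two-condition crossover designs with 80%
    credible intervals, semi-partial R2 effect sizes and percentile
    conditional effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
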