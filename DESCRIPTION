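Package: cuephys
Title: Spike-Train and Behavioral Analysis of Dopamine Cue Reactivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for ventral tegmental area (VTA) single-unit
    recordings in Pavlovian and operant cue-reward tasks. Provides a
    documented session container with CSV/JSON readers and validation,
    peri-event histograms with causal exponential smoothing, auROC-based
    response normalization against pre-event baselines, an activity-based
    putative-dopamine-neuron classification cascade (PCA, Ward-linkage
    hierarchical clustering, k-means refinement, baseline-rate exclusion),
    waveform and burst statistics, behavioral cue-reactivity metrics
    (lever-press hazard rates, port occupancy, accuracy and congruence
    indices, progressive-ratio breakpoints), a bootstrap centroid-distance
    similarity test with a shuffled-label null distribution, and an
    inhomogeneous-Poisson/gamma-renewal session simulator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
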