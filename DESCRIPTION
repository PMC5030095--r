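Package: locomod
Title: Locomotion Modulation Analysis for Two-Photon Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how locomotion modulates the activity of visual
    cortical neurons recorded with two-photon calcium imaging across
    sensory contexts (darkness, grey screen, grating stimulation). From
    raw ROI fluorescence and treadmill speed it computes neuropil-corrected
    Delta-F/F0 traces, segments behavior into stationary and locomotion
    periods with a three-criterion speed rule, derives per-neuron
    locomotion modulation indices with autocorrelation-adjusted bootstrap
    confidence intervals, classifies neurons as context-dependent or
    context-independent using odd/even epoch reliability, and aggregates
    per-animal summaries with rank-based population tests. Includes a
    seeded synthetic-data generator (Poisson spiking through a calcium
    indicator forward model) with ground-truth labels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
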