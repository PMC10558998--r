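Package: hyperbis
Title: Inter-Brain Bispectral Synchrony Analysis for Hyperscanning EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify inter-brain synchrony in multi-participant
    (hyperscanning) EEG recordings through windowed diagonal cross-bispectrum
    estimation. Provides a synthetic session generator with ground-truth
    quadratic phase coupling, readers and writers for EDF and BrainVision
    recordings and for session containers, a preprocessing chain (resampling,
    zero-phase Butterworth filtering, line-noise removal, robust average
    referencing, H-infinity adaptive ocular-artifact cancellation), rest-
    normalized bispectral representations with canonical EEG band summaries,
    mass right-tailed Wilcoxon discovery of synchronized channel combinations
    with Bonferroni control, event-locked synchronized/desynchronized
    performance comparison, and region-of-interest spatial aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
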