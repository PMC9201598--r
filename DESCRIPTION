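Package: lamindev
Title: Laminar Electrophysiology Pipeline for Developing Barrel Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-channel extracellular recordings from
    developing rodent somatosensory cortex. Provides current-source density
    estimation with Vaknin boundary correction and spatial Hamming smoothing,
    granular-layer localization from the earliest large sink, 50 Hz line-noise
    channel quality control, spindle-burst detection via a Hilbert envelope
    threshold with duration and trough screening, Welch band-power spectra with
    area normalization, event-aligned Morlet wavelet spectrograms, sensory-evoked
    LFP and multi-unit response metrics (peak amplitude and latency, peri-stimulus
    time histograms, paired-pulse ratios), and PCA plus k-means developmental
    staging with silhouette-based model selection. A synthetic-recording generator
    with complete ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
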