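Package: slicephys
Title: Burst, Coupling and Intrinsic-Excitability Analysis for Brain-Slice
    Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for characterizing neocortical
    hyperexcitability in brain-slice recordings: detection of spontaneous
    epileptiform bursts in local field potentials by envelope thresholding,
    Morlet-wavelet time-frequency maps and phase-amplitude cross-frequency
    coupling (normalized Kullback-Leibler modulation index) with
    block-shuffle surrogate significance, inter-layer lag estimation by
    band-limited cross-correlation, postsynaptic-current event detection
    with amplitude/kinetics measurement and reversal-potential fits, and
    extraction of intrinsic membrane and action-potential properties from
    current-clamp step protocols.  A seeded synthetic-data generator with
    machine-readable ground truth makes the whole pipeline testable
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
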