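Package: voltsync
Title: Synchronous Ensemble Analysis for Population Voltage Imaging of
    Hippocampal CA1
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for population voltage imaging of hippocampal
    CA1 pyramidal cells recorded together with a contralateral LFP channel and
    behavior tracking. Converts negative-going fluorescence to dF/F, detects
    spikes against a noise-derived threshold, extracts subthreshold membrane
    voltage, segments behavioral states, detects population-synchrony events
    against jittered surrogates, computes grand-average and pairwise
    cross-correlograms with synchronization strength, detects ripples and
    quantifies ripple and theta modulation via Hilbert phase statistics,
    measures pairwise subthreshold theta coherence, and characterizes
    place-field organization by circular variance. A synthetic session
    generator with a ground-truth ledger makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
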