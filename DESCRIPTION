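Package: fastball
Title: Frequency-Tagging EEG Analysis of Recognition Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of fast periodic visual stimulation (FPVS)
    oddball EEG experiments that index recognition memory. Builds and
    validates stimulus schedules (3 Hz image streams with a 0.6 Hz oddball),
    preprocesses raw multichannel recordings (common-average reference,
    zero-phase low-pass filtering, polyphase resampling, integer-cycle
    epoching, polynomial detrending, amplitude-threshold artifact
    suppression with half-Hanning tapers), computes neighbour-bin
    signal-to-noise spectra and the F / f+ steady-state summary metrics with
    data-driven harmonic selection, scores the accompanying behavioural
    instruments (2AFC, PVT, DMS-48, ACE-III norms), and provides the group
    inferential layer (type-III ANCOVA, Kruskal-Wallis with Bonferroni
    post hocs, bootstrap regression, two-way mixed-model intraclass
    correlations). A synthetic-data module generates cohorts of
    steady-state EEG recordings with known ground truth for validation and
    power exploration.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    car,
    jsonlite,
    yaml,
    data.table,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
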