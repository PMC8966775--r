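Package: fictiveswim
Title: Extraction and Quantification of Fictive Swim Episodes from Dual
    Ventral-Root Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing fictive locomotion in paralyzed zebrafish
    larvae recorded with paired extracellular electrodes on contralateral
    hemi-segments. Implements Morlet continuous-wavelet denoising of raw
    voltage traces, unbiased swim-episode extraction by peak detection and
    temporal clustering, burst segmentation, left-right alternation and
    simultaneous-burst penalty scores, band-passed envelope and periodicity
    activity traces, wavelet-ridge instantaneous tail-beat frequency, circular
    phase-shift and coherence statistics, bout classification by frequency
    trajectory and 30 Hz speed-module crossing, and calcium dF/F alignment
    with electrophysiology including lag estimation. A seeded synthetic
    recording generator with full ground-truth annotation emulates the burst
    structure, stimulation presets and artefact classes of real recordings so
    that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    pracma,
    zoo,
    jsonlite,
    rlang,
    tibble,
    dplyr,
    readr
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
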