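Package: scpnscreen
Title: High-Content Screen Analysis of Cortical Neuron Subtype Refinement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis of image-based high-content screens that
    quantify refinement of subcerebral projection neuron (SCPN) identity from
    multichannel immunofluorescence of cultured cortical neurons. Provides a
    seeded synthetic plate generator (multichannel TIFF fields plus per-nucleus
    ground truth), Hoechst-based nucleus segmentation with clump splitting,
    per-nucleus viability filtering and per-well toxicity grading, band- and
    fraction-of-maximum intensity classification of transcription-factor
    markers (CTIP2, SATB2, CTIP1), the CTIP2+/SATB2- to CTIP2+/SATB2+
    refinement-ratio statistic with condition-specific plate normalization,
    replicate statistics, and three-level candidate triage with ranked hit
    reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
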