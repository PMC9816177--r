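Package: crossadapt
Title: Cross-Feature Adaptation Analysis for Visual Cortical Population Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying rapid cross-feature adaptation in visual cortical
    (area V4) population recordings. Provides synthetic-data generators for tuned
    spiking populations with controllable adaptation effects, patch-structured
    natural-scene surrogates and free-viewing eye traces; Sobel-filter orientation
    scoring and colour classification of image patches; scanpath simulation and
    iso- versus cross-feature saccade statistics; velocity-threshold fixation
    detection and pseudo-trial extraction; circular tuning statistics (selectivity
    index, Rayleigh test, preferred angle, sliding-window tuning latency); and
    population-level statistics (pairwise noise correlations, projected
    principal-component variance ratios, cross-validated linear-discriminant
    decoding), together with end-to-end pipelines that mirror the passive-fixation,
    free-viewing and natural-scene experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
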