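Package: httscreen
Title: High-Content Screening Analysis for Huntingtin Aggregation and
    Neurite Morphology in Primary Neuronal Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for high-content screens of
    polyglutamine-expanded Huntingtin (Htt) toxicity in Drosophila primary
    neuronal cultures imaged in two fluorescence channels (membrane-GFP
    morphology, Htt-RFP reporter). Segments neuronal cell-body clusters
    (neuromeres) and neurites, counts aggregate pixels above a calibrated
    intensity threshold, builds an eight-metric morphology profile by
    Gaussian-mixture area binning and K-means length grouping, and calls
    hits in two stages: aggregation suppression (plate-normalised log2
    aggregate ratio, Welch t-test, 2-SD screen cutoff) followed by
    morphology reversion toward the non-pathogenic control (per-feature
    t-tests combined by Fisher's method). Includes a synthetic two-channel
    culture-field and whole-screen generator with ground truth so every
    stage is testable without original microscope images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    tiff,
    EBImage,
    igraph,
    jsonlite,
    readr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
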