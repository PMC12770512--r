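Package: cytopipe
Title: Preprocessing, Feature Extraction and Hybrid Classification of
    Single-Cell Lung Cytology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for three-class lung-cancer subtype
    classification from grayscale single-cell microscopy images. Provides a
    seeded synthetic image generator with class-specific morphological motifs,
    deterministic image standardisation and enhancement (grayscale conversion,
    bilinear resizing, contrast-limited adaptive histogram equalisation, 3x3
    median denoising), a bespoke feature-processing stage (dark-pixel
    pre-mapping, Otsu foreground separation, size-filtered mask cleanup,
    three-way image composition, midtone lightening), stratified dataset
    sealing/splitting/k-fold utilities, a seeded affine augmentation stack, a
    desk-scale hybrid two-branch neural classifier (residual global branch plus
    attention-gated encoder-decoder branch fused into a dense head), and an
    evaluation layer with confusion-matrix metrics and cross-validation
    confidence statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
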