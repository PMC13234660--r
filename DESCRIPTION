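Package: vocsim
Title: Cosine-Similarity Identification of Volatile Organic Compounds from Plasma Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Identifies volatile organic compounds (VOCs) from still RGB images of a
    helium dielectric-barrier-discharge plasma. Images are cropped to named regions,
    segmented into a grid of equal blocks, summarised as per-block mean-RGB feature
    vectors, and classified by maximum cosine similarity against per-category average
    feature vectors. Ships a seeded synthetic plasma-image generator emulating the
    dark background, coloured light columns, pressure-dependent hue shifts and bottom
    reflection band of real plasma frames, so the full pipeline is testable without
    the original dataset. Provides tidy evaluation reports, similarity-matrix
    heatmaps, block-averaged image reconstruction, and a block-count sweep mirroring
    the accuracy-versus-resolution experiment design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils,
    yaml
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
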