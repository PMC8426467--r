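Package: histotile
Title: Headless Pre-Processing of Histology Image Tiles for Deep Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A scriptable toolkit for preparing haematoxylin-and-eosin (H&E)
    image tiles for convolutional neural network training. Provides grid
    patching of larger images with coordinate-stamped file names, tissue
    versus whitespace estimation by fixed, Otsu or adaptive thresholding
    with coverage-based tile filtering, class balancing by seeded dihedral
    (flip/rotate) augmentation or reduction, stain normalisation by
    per-channel cumulative-histogram matching, a small catalogue of
    pixel-level augmentation operators centred on embossing, and an
    evaluation layer that aggregates per-tile class probabilities to
    region-of-interest and patient level by majority voting with
    confusion-matrix metrics, rank-based ROC AUC, exact binomial intervals
    and Fleiss' kappa. Includes deterministic synthetic fixture generators
    (oriented fibre textures, whitespace tiles, stain-shifted batches) so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    generics,
    dplyr,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    EBImage,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
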