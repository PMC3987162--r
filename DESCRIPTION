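Package: cmcseg
Title: Chaotic Map Clustering Segmentation of Mammographic Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature-space segmentation of grayscale mammographic images by
    synchronization clustering of coupled chaotic logistic maps. Images are
    tiled into pixel squares, per-tile intensity and co-occurrence texture
    features are extracted, standardized and decorrelated, and one chaotic
    map is attached to each tile with a Gaussian coupling in feature space.
    Pairs of maps are clustered by thresholding the mutual information of
    their sign-bit sequences; the threshold hierarchy is scanned for a
    stability plateau, the selected partition is projected back to the image
    with spatial-contiguity enforcement and reserved background, border and
    normal-tissue clusters, and small isolated candidate clusters are
    flagged as mass-like findings. Includes a seeded synthetic phantom
    generator with ground truth, a Euclidean-distance clustering baseline,
    and evaluation tools (ROI overlap fractions, overlap histograms,
    confusion counts and accuracies).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    png,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
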