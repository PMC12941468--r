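Package: shellcarbon
Title: Non-Destructive Shell Carbonate Carbon Quantification from Panel Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the carbonate carbon stored in the shells of hard-shelled
    fouling organisms (barnacles and bivalves) on settlement panels from
    instance-segmentation masks, without destructive sampling. Converts each
    instance mask to projected shell length and width via the minimum-area
    rotated rectangle, maps the equivalent projected area to shell dry weight
    through species-specific allometric power laws, and multiplies by measured
    carbonate carbon fractions to obtain per-individual and per-panel carbon
    storage. Also provides sliding-window tiling with instance stitching for
    large images, a classical watershed baseline segmenter, a COCO-protocol
    segmentation metric suite (IoU, Dice, precision, recall, mAP), readers and
    writers for LabelMe and COCO instance annotations, and a synthetic panel
    scene generator with pixel-perfect ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    minpack.lm,
    EBImage,
    png,
    tiff,
    stats,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
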