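Package: mechanoquant
Title: Quantification of Collagen Alignment, Yap Localization and Matrix
    Deformation in Organoid Invasion Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image quantification toolkit for collective invasion assays of
    tumor organoids embedded in fibrillar collagen. Implements per-cell Yap
    nuclear-to-cytoplasmic ratio measurement on segmented multichannel
    confocal planes (organoid masking, nucleus detection, seeded watershed
    cell segmentation, outer/inner layer classification, K14 high/low and
    rim/leader cell classification), structure-tensor estimation of local
    fiber orientation and coherency with the nematic scalar order parameter
    evaluated in rim-anchored regions of interest, convex-hull protrusive
    index and strand morphometrics of tumor borders, and drift-corrected
    tracking of matrix-embedded beads with displacement toward the organoid
    body. A synthetic-image generator produces organoids, fiber fields,
    bead time-lapses and border masks with exact ground truth so that every
    stage of the analysis can be validated without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    jsonlite,
    igraph,
    stats,
    utils,
    grDevices,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
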