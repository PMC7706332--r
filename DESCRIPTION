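Package: hyperseg
Title: Organ-Level Semantic Segmentation of Hyperspectral Plant Images
    and Downstream Quantitative Genetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-pixel classification of hyperspectral images of grain
    crops into background, leaf, stalk and panicle classes; whole-image
    semantic segmentation; extraction of seven organ-level morphological
    traits from segmentation maps; and downstream quantitative genetics
    (genomic relationship matrices, REML heritability as proportion of
    variance explained, and single-marker association scans with
    principal-component and kinship control). Includes a synthetic-data
    module that generates hyperspectral plant cubes with ground-truth
    organ masks, click-style pixel annotations, genotype matrices and
    phenotypes with known additive genetic architecture, so that every
    stage of the pipeline can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    nnet,
    e1071,
    randomForest,
    glmnet,
    mixOmics,
    png,
    tiff,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
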