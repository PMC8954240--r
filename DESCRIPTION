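Package: cosreg
Title: Multimodal Deformable Image Registration with a Joint Co-Sparse
    Analysis Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deformable registration of paired 2D images from different
    modalities (photoacoustic, MR, ultrasound) driven by a joint co-sparse
    analysis model: a pair of over-complete analysis operators with unit-norm
    rows, one per modality, is learned from co-located image patches by the
    alternating direction method of multipliers, and a free-form deformation
    is then optimized under the coupled co-sparsity cost. Includes a
    normalized-mutual-information baseline registrar sharing the same
    optimization scaffold, a brain-mimicking phantom simulator with embedded
    vessels and smooth ground-truth deformations, and evaluation by
    displacement RMSE, target registration error and the 95th-percentile
    Hausdorff distance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    png,
    tiff,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
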