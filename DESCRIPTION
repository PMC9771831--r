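Package: cerebseg
Title: Cerebellum Sub-Segmentation with 2.5D Multi-View Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lobule-level segmentation of the cerebellum from isotropic
    T1-weighted-style volumes. Implements a 27-structure labeling protocol
    (hemispheric lobules, vermal sub-segments, and cerebellar white matter),
    bounding-box localization, 2.5D slicing with spatial information
    aggregation (7-channel stacks), a small trainable encoder-decoder
    reference network per anatomical view, probability-space view
    aggregation, an MRI augmentation stack (in-slice affine, left-right flip
    with label swapping, polynomial bias fields, non-linear deformation),
    and an evaluation suite (Dice, Hausdorff and robust Hausdorff distance,
    volume similarity, test-retest ICC). A procedural cerebellum phantom
    generator provides ground-truth data so the whole pipeline can be
    exercised end-to-end without any imaging download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
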