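Package: pancatlas
Title: Abdominal CT Atlas Construction with Dense Displacement Registration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for building population-average abdominal computed
    tomography (CT) atlases optimized for the pancreas. Provides body-part
    score based field-of-view cropping, two-stage registration (block-matching
    affine with trimmed least squares, then dense-displacement-sampling
    deformable registration driven by quantized self-similarity context
    descriptors and exact tree-based discrete optimization), weighted
    sliding-window template averaging, variance mapping, majority-vote label
    fusion, inverse label transfer, and Dice/Hausdorff evaluation. Includes a
    deterministic synthetic abdominal phantom generator so every stage can be
    exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    oro.nifti
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
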