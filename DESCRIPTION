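Package: corovox
Title: Coronary-Style Vessel Segmentation with a Dense-Residual Local-Contextual-Transformer 3-D U-Net
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for segmenting thin tubular vessels (coronary-artery style)
    in 3-D CT angiography volumes. Implements a 3-D U-shaped convolutional
    network whose skip connections carry a local contextual transformer (LCT)
    attention block and whose encoder/decoder stages use dense residual (DR)
    convolution blocks, trained with a deep-supervision Dice objective and
    piecewise learning-rate and supervision-weight schedules. Includes
    Hounsfield-unit windowing and sliding-block NIfTI inference, voxel-overlap
    and surface-distance evaluation metrics (Dice, recall, precision, average
    symmetric surface distance, Hausdorff distance), and a seeded synthetic
    vascular-phantom generator so the whole pipeline can be exercised without
    clinical data. The network runtime (grouped 3-D convolutions, pooling,
    transposed convolutions, instance normalisation, softmax, backpropagation
    and Adam) is implemented in compiled code within the package.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
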