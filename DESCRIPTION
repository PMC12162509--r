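Package: resunet3d
Title: Residual 3D U-Net with Deep Supervision for Multi-Region Brain Tumor Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Volumetric encoder-decoder networks for BraTS-style brain tumor
    segmentation from multi-modal MRI. Implements four 3D U-Net variants
    (plain, residual, attention-gated, and autoencoder-regularized) with
    deep-supervision output heads, the overlapping-region target encoding
    (whole tumor, tumor core, enhancing tumor), batch Dice plus binary
    cross-entropy or focal composite losses, patch-based training with Adam
    and plateau scheduling, half-overlap sliding-window inference with
    Gaussian center weighting and eight-flip test-time augmentation, and the
    threshold/connected-component post-processing that maps region
    probabilities back to integer labels. A deterministic ellipsoid phantom
    generator provides synthetic multi-modal cases so the full pipeline is
    testable without any external dataset. The neural-network core (3D
    convolutions via im2col, reverse-mode automatic differentiation,
    instance normalization, Adam) is implemented in the package with
    compiled kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
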