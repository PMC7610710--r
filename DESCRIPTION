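Package: sfcn
Title: Lightweight Fully Convolutional Networks for Brain-Age Prediction
    from 3D Structural MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the Simple Fully Convolutional Network (SFCN)
    approach to brain-age prediction from T1-weighted structural MRI:
    a lightweight 3D convolutional architecture trained as a soft
    classifier over discretized age bins with a Kullback-Leibler
    divergence loss, voxel-shift and sagittal-mirror augmentation, an
    SGD recipe with step learning-rate decay, semi-multimodal model
    ensembling, and a transferable linear correction for the
    systematic age-dependent bias of brain-age deltas. Includes 3D
    ResNet comparison builders, evaluation metrics with bootstrap
    uncertainty, NIfTI volume input/output, and a seeded generator of
    synthetic brain phantoms whose morphology encodes age and sex, so
    the whole pipeline is testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    oro.nifti
SystemRequirements: C++17
Config/testthat/edition: 3
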