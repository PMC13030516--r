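Package: spinessl
Title: Semi-Supervised Joint Vertebra Segmentation and Identification for Spinal CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, CPU-trainable implementation of semi-supervised joint
    vertebra segmentation and level identification for 3D spinal CT. Provides a
    dual-branch 3D encoder-decoder network (shared encoder, long-range bottleneck
    sequence operator, deep-supervised segmentation decoder, attention-augmented
    identification decoder), teacher-student consistency training with ramped
    pseudo-label confidence thresholds and an EMA teacher, Gaussian-heatmap
    centroid regression, anatomically constrained sequence post-processing, and
    instance-level IoU-matched evaluation metrics. Ships a synthetic spine-phantom
    generator so every component is testable without external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    yaml,
    EBImage,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
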