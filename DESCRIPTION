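Package: fracturekit
Title: Two-Stage Rib Fracture Recognition in CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for volumetric rib-fracture recognition in
    computed tomography. Stage one trains an encoder-decoder segmenter
    (leaky-ReLU / instance-norm U-Net family, with an optional coarse-to-fine
    cascade) under a composite Dice + cross-entropy + contour-length loss and
    predicts whole volumes by sliding-window patch inference with per-voxel
    maximum fusion. Stage two re-scores the resulting candidate regions with
    dense-connectivity 3D classifiers at three crop scales, fusing their
    probabilities by validation-accuracy weights, to exclude false positives.
    Includes a seeded CT-like phantom generator (rib-like tubes, instance
    labelled lesions, off-rib decoy blobs), NIfTI-1 input/output, fingerprint
    driven preprocessing (resampling, Hounsfield-unit percentile clipping,
    z-score normalisation), and surface-distance evaluation metrics (Dice,
    IoU, ASSD, Hausdorff).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
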