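Package: ellipseg
Title: Weakly Supervised Brain Tumor Segmentation with Ellipse-Box Trimaps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for training a binary tumor segmenter from cheap ellipse-box
    annotations instead of exact per-pixel masks. Fits moment-matching ellipses
    to rough tumor localizations, derives foreground/background/ignore trimaps
    by shrinking (x0.9) and enlarging (x1.2) the ellipse, and trains a
    multi-stream U-Net (one encoder-decoder stream per MRI modality with
    feature-level fusion) in two rounds: coarse training on trimap weak labels
    followed by refinement on a small annotated subset. Includes a synthetic
    multi-modality phantom generator with ground-truth masks, strict
    patient-separated data splitting, pixel-pooled segmentation metrics (dice,
    Jaccard, tumor accuracy, confusion matrices), and a degradation report
    comparing the weakly supervised protocol against fully supervised training.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
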