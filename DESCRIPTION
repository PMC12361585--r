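Package: lesioncascade
Title: Multi-Instance Lung Lesion Segmentation with Cascade
    False-Positive Reduction for Thoracic CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A three-stage pipeline for automatic segmentation of all lung
    lesions in a thoracic CT scan: thoracic bounding-box cropping from a
    lung mask with per-dimension minimum-size fallback, pluggable binary
    lesion segmentation followed by 26-connectivity instance labeling, and
    a two-classifier cascade (extrapulmonary classifier and lesion
    validator) that removes false-positive candidates from the predicted
    mask. Includes a seedable synthetic thoracic CT phantom generator with
    ground-truth lesion instances, a candidate-dataset builder and
    stratified cross-validation trainer for the cascade classifiers, and
    the full multi-lesion evaluation protocol: overlap-based detection
    metrics, image- and lesion-level Dice, 95th-percentile Hausdorff
    distance, FROC analysis, lesion volume agreement (R-squared and
    Bland-Altman), and case-level bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    withr,
    pROC
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    oro.nifti,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
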