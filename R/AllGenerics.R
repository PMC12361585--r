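# Generics for the package's S4 surface.

#' @rdname voxelData
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname voxelSpacing
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname voxelOrigin
#' @export
setGeneric("voxelOrigin", function(x) standardGeneric("voxelOrigin"))

#' @rdname gridShape
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' @rdname physicalExtent
#' @export
setGeneric("physicalExtent",
           function(x, axis = NULL) standardGeneric("physicalExtent"))

#' @rdname nInstances
#' @export
setGeneric("nInstances", function(x) standardGeneric("nInstances"))

#' Fit a segmentation backend on paired crops and binary ground truth
#'
#' @param backend a [SegmentationBackend-class].
#' @param volumes list of [CTVolume-class] crops.
#' @param masks list of grid-congruent [BinaryMask-class] ground truths.
#' @param ... backend-specific options.
#' @return the trained backend.
#' @export
setGeneric("fitBackend",
           function(backend, volumes, masks, ...) standardGeneric("fitBackend"))

#' Predict a binary lesion mask on a (cropped) CT volume
#'
#' @param backend a trained [SegmentationBackend-class].
#' @param ct a [CTVolume-class].
#' @return a [BinaryMask-class] grid-congruent with `ct`.
#' @export
setGeneric("predictMask",
           function(backend, ct) standardGeneric("predictMask"))

#' @rdname isTrained
#' @export
setGeneric("isTrained", function(x) standardGeneric("isTrained"))

#' Probability that a candidate patch pair is a true lesion
#'
#' Classifiers output `P(class 1)`, class 1 being "true lesion" by the
#' candidate-labeling convention (candidates matching a ground-truth lesion
#' are labeled 1, non-matching candidates 0).
#'
#' @param classifier a [CandidateClassifier-class].
#' @param pair a [CandidatePatchPair-class] (or list of them).
#' @return numeric probability (or vector) in [0, 1].
#' @export
setGeneric("predictProb",
           function(classifier, pair) standardGeneric("predictProb"))

#' Train a cascade classifier on labeled candidate patch pairs
#'
#' @param classifier a [CandidateClassifier-class].
#' @param pairs list of [CandidatePatchPair-class].
#' @param labels integer vector of 0/1 candidate labels.
#' @param config a [TrainConfig-class].
#' @param valPairs,valLabels optional held-out pairs for early stopping; when
#'   omitted a stratified fraction of `pairs` is held out.
#' @param seed RNG seed.
#' @return the trained classifier, with the training curve in
#'   `trainingCurve(classifier)`.
#' @export
setGeneric("fitClassifier",
           function(classifier, pairs, labels, config = trainConfig(),
                    valPairs = NULL, valLabels = NULL, seed = 1L)
             standardGeneric("fitClassifier"))

#' @rdname trainingCurve
#' @export
setGeneric("trainingCurve", function(x) standardGeneric("trainingCurve"))
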