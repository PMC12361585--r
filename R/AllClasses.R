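#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib lesioncascade, .registration = TRUE
NULL

# ---- core spatial containers -------------------------------------------------

#' Virtual parent of all voxel-grid objects
#'
#' A 3-D array together with per-axis voxel spacing and a physical origin,
#' both in millimetres. The axis order is fixed anatomically:
#' x = left-right, y = anterior-posterior, z = inferior-superior.
#' Voxel `(i, j, k)` (1-based) has its center at
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @slot data 3-D array.
#' @slot spacing numeric(3), mm per voxel, strictly positive.
#' @slot origin numeric(3), mm.
#' @exportClass VoxelGrid
setClass("VoxelGrid", representation("VIRTUAL",
  data = "array", spacing = "numeric", origin = "numeric"))

.validGrid <- function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L)
    msg <- c(msg, "data must be a 3-D array")
  else if (any(d < 1L))
    msg <- c(msg, "all three array extents must be >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive finite values")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite values")
  if (length(msg)) msg else TRUE
}
setValidity("VoxelGrid", .validGrid)

#' CT volume in Hounsfield units
#'
#' @inheritSection VoxelGrid description
#' @examples
#' ct <- CTVolume(array(-1000, c(4, 4, 2)), spacing = c(0.7, 0.7, 3))
#' physicalExtent(ct)
#' @exportClass CTVolume
setClass("CTVolume", contains = "VoxelGrid")

#' Binary lesion mask (0 = background / normal tissue, 1 = lesion)
#' @exportClass BinaryMask
setClass("BinaryMask", contains = "VoxelGrid")
setValidity("BinaryMask", function(object) {
  v <- unique(as.vector(object@data))
  if (!all(v %in% c(0, 1))) "mask values must be 0 or 1" else TRUE
})

#' Instance-labeled lesion mask
#'
#' Non-negative integer voxels; 0 is background and each positive label
#' is one lesion instance (one 26-connected component when produced by
#' [labelInstances()]). The producing operations ([labelInstances()],
#' [runCfpr()]) emit contiguous labels `1..n`; cropping a labeled mask
#' preserves label identity and may therefore leave gaps, which the
#' container tolerates.
#' @exportClass InstanceMask
setClass("InstanceMask", contains = "VoxelGrid")
setValidity("InstanceMask", function(object) {
  v <- as.vector(object@data)
  if (any(v < 0) || any(v != round(v)))
    return("instance labels must be non-negative integers")
  TRUE
})

#' @rdname VoxelGrid-class
#' @param data 3-D array.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param origin numeric(3) physical origin in mm.
#' @export
CTVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("CTVolume", data = .as3d(data), spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' @rdname BinaryMask-class
#' @inheritParams CTVolume
#' @export
BinaryMask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  d <- .as3d(data)
  storage.mode(d) <- "integer"
  new("BinaryMask", data = d, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' @rdname InstanceMask-class
#' @inheritParams CTVolume
#' @export
InstanceMask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  d <- .as3d(data)
  storage.mode(d) <- "integer"
  new("InstanceMask", data = d, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

.as3d <- function(x) {
  if (is.null(dim(x))) stop("data must be an array")
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3L) stop("expected 3D volume")
  x
}

# ---- geometry ---------------------------------------------------------------

#' Axis-aligned voxel bounding box, 1-based inclusive corners
#'
#' Physical side length along axis a is `(hi[a] - lo[a] + 1) * spacing[a]`.
#'
#' @slot lo integer(3) inclusive lower corner (1-based voxel indices).
#' @slot hi integer(3) inclusive upper corner.
#' @exportClass BoundingBox3D
setClass("BoundingBox3D", representation(lo = "integer", hi = "integer"))
setValidity("BoundingBox3D", function(object) {
  if (length(object@lo) != 3L || length(object@hi) != 3L)
    return("lo and hi must have length 3")
  if (any(object@lo < 1L)) return("corners must be >= 1")
  if (any(object@hi < object@lo)) return("lo must be <= hi componentwise")
  TRUE
})

#' @rdname BoundingBox3D-class
#' @param lo,hi integer(3) inclusive voxel corners.
#' @export
BoundingBox3D <- function(lo, hi) {
  new("BoundingBox3D", lo = as.integer(lo), hi = as.integer(hi))
}

#' Record of a crop, sufficient to pad results back to the original grid
#'
#' @slot lo integer(3), 1-based offset of the crop in the original grid.
#' @slot originalShape integer(3), shape of the original grid.
#' @exportClass CropRecord
setClass("CropRecord",
         representation(lo = "integer", originalShape = "integer"))

#' @rdname CropRecord-class
#' @param lo integer(3) crop offset (1-based).
#' @param originalShape integer(3) original grid shape.
#' @export
CropRecord <- function(lo, originalShape) {
  new("CropRecord", lo = as.integer(lo),
      originalShape = as.integer(originalShape))
}

# ---- configuration objects --------------------------------------------------

#' Thoracic bounding-box configuration
#'
#' `minExtentMm` holds the per-dimension minimum physical size of an
#' acceptable lung bounding box; a predicted box smaller than the minimum
#' along an axis falls back to the whole image on that axis. Defaults are
#' 210, 150 and 120 mm for x, y, z, the smallest plausible adult lung
#' extents.
#'
#' @slot minExtentMm numeric(3), mm.
#' @exportClass BboxConfig
setClass("BboxConfig", representation(minExtentMm = "numeric"),
         prototype(minExtentMm = c(210, 150, 120)))
setValidity("BboxConfig", function(object) {
  if (length(object@minExtentMm) != 3L || any(object@minExtentMm <= 0))
    "minExtentMm must be 3 strictly positive values" else TRUE
})

#' @rdname BboxConfig-class
#' @param minExtentMm numeric(3) minimum box extents in mm.
#' @export
bboxConfig <- function(minExtentMm = c(210, 150, 120)) {
  new("BboxConfig", minExtentMm = as.numeric(minExtentMm))
}

#' Cascade false-positive-reduction configuration
#'
#' `thrE` gates the extrapulmonary classifier (XPC): a candidate whose
#' extrapulmonary score `1 - P(lesion)` is at or above `thrE` is dropped.
#' Candidates passing XPC are kept only if the lesion-validator (LVC)
#' probability strictly exceeds `thrI`. Patch geometry follows the
#' classifiers' input conventions: a 128 x 128 coronal patch at 1 x 1 mm for
#' XPC and a 96 mm cube resampled to 96^3 at 1 mm isotropic for LVC.
#'
#' Threshold sentinels outside [0, 1] are permitted so that a configuration
#' can force pass-all (`thrE > 1`, `thrI < 0`) or drop-all behavior.
#'
#' @slot thrE,thrI numeric thresholds.
#' @slot xpcSize integer(2) XPC patch shape in pixels.
#' @slot lvcSize integer(3) LVC patch shape in voxels.
#' @slot patchSpacingMm numeric, isotropic patch resolution (mm).
#' @exportClass CascadeConfig
setClass("CascadeConfig",
  representation(thrE = "numeric", thrI = "numeric", xpcSize = "integer",
                 lvcSize = "integer", patchSpacingMm = "numeric"),
  prototype(thrE = 0.5, thrI = 0.5, xpcSize = c(128L, 128L),
            lvcSize = c(96L, 96L, 96L), patchSpacingMm = 1))

#' @rdname CascadeConfig-class
#' @param thrE,thrI cascade thresholds.
#' @param xpcSize integer(2); XPC patch shape.
#' @param lvcSize integer(3); LVC patch shape.
#' @param patchSpacingMm isotropic patch resolution in mm.
#' @export
cascadeConfig <- function(thrE = 0.5, thrI = 0.5, xpcSize = c(128, 128),
                          lvcSize = c(96, 96, 96), patchSpacingMm = 1) {
  new("CascadeConfig", thrE = thrE, thrI = thrI,
      xpcSize = as.integer(xpcSize), lvcSize = as.integer(lvcSize),
      patchSpacingMm = patchSpacingMm)
}

#' Pass-through cascade configuration (keeps every candidate)
#' @param ... passed to [cascadeConfig()].
#' @export
passThroughCascade <- function(...) cascadeConfig(thrE = 1.01, thrI = -0.01, ...)

#' Candidate patch pair fed to a cascade classifier
#'
#' The raw channel is min-max normalized to [0, 1]; the mask channel carries
#' only the candidate under evaluation.
#'
#' @slot raw,mask arrays of identical shape.
#' @slot geometry `"2D-coronal"` or `"3D-crop"`.
#' @exportClass CandidatePatchPair
setClass("CandidatePatchPair",
         representation(raw = "array", mask = "array", geometry = "character"))
setValidity("CandidatePatchPair", function(object) {
  msg <- character()
  if (!identical(dim(object@raw), dim(object@mask)))
    msg <- c(msg, "raw and mask must have the same shape")
  rng <- range(object@raw)
  if (is.finite(rng[1]) && (rng[1] < -1e-9 || rng[2] > 1 + 1e-9))
    msg <- c(msg, "raw values must lie in [0, 1]")
  if (!object@geometry %in% c("2D-coronal", "3D-crop"))
    msg <- c(msg, "geometry must be '2D-coronal' or '3D-crop'")
  if (length(msg)) msg else TRUE
})

#' Classifier training configuration
#'
#' Binary cross-entropy loss, Adam optimization with learning rate 1e-3 and
#' weight decay 1e-4, batch size 32, early stopping after 30 epochs without
#' validation-loss improvement, and random augmentation (translation, flip,
#' zoom, Gaussian noise) of training patches.
#'
#' @slot lr,weightDecay,noiseSd numeric.
#' @slot balanceClasses class-balance the loss (default TRUE).
#' @slot batchSize,patience,maxEpochs,hidden,augmentCopies integer.
#' @slot maxShiftFrac,maxZoom numeric augmentation ranges.
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(lr = "numeric", weightDecay = "numeric",
                 batchSize = "integer", patience = "integer",
                 maxEpochs = "integer", hidden = "integer",
                 augmentCopies = "integer", maxShiftFrac = "numeric",
                 maxZoom = "numeric", noiseSd = "numeric",
                 balanceClasses = "logical"),
  prototype(lr = 1e-3, weightDecay = 1e-4, batchSize = 32L, patience = 30L,
            maxEpochs = 300L, hidden = 16L, augmentCopies = 2L,
            maxShiftFrac = 0.1, maxZoom = 0.15, noiseSd = 0.02,
            balanceClasses = TRUE))
setValidity("TrainConfig", function(object) {
  if (object@patience < 1L) return("patience must be >= 1")
  if (object@batchSize < 1L) return("batch size must be >= 1")
  TRUE
})

#' @rdname TrainConfig-class
#' @param lr learning rate.
#' @param weightDecay L2 weight decay.
#' @param batchSize minibatch size.
#' @param patience early-stopping patience in epochs.
#' @param maxEpochs hard epoch cap.
#' @param hidden hidden-layer width of the dense network.
#' @param augmentCopies augmented copies generated per training patch.
#' @param maxShiftFrac maximum translation, as a fraction of patch size.
#' @param maxZoom maximum zoom factor deviation from 1.
#' @param noiseSd Gaussian noise SD added to normalized intensities.
#' @param balanceClasses weight the binary cross-entropy so both classes
#'   contribute equally regardless of their frequencies (candidate sets
#'   are typically non-lesion-heavy).
#' @export
trainConfig <- function(lr = 1e-3, weightDecay = 1e-4, batchSize = 32,
                        patience = 30, maxEpochs = 300, hidden = 16,
                        augmentCopies = 2, maxShiftFrac = 0.1,
                        maxZoom = 0.15, noiseSd = 0.02,
                        balanceClasses = TRUE) {
  new("TrainConfig", lr = lr, weightDecay = weightDecay,
      batchSize = as.integer(batchSize), patience = as.integer(patience),
      maxEpochs = as.integer(maxEpochs), hidden = as.integer(hidden),
      augmentCopies = as.integer(augmentCopies), maxShiftFrac = maxShiftFrac,
      maxZoom = maxZoom, noiseSd = noiseSd,
      balanceClasses = balanceClasses)
}

# ---- phantom ----------------------------------------------------------------

#' Synthetic thoracic phantom specification
#'
#' Defaults emulate the heterogeneous multicenter cohort regime at desk
#' scale: a 384 x 384 x 200 mm field of view, lesion diameters drawn from
#' 10-26 mm, and two lesions per scan in expectation (see the methods
#' vignette for the rationale behind every default).
#'
#' @slot shape integer(3) grid shape.
#' @slot spacing numeric(3) voxel spacing, mm.
#' @slot nLesions integer, number of ground-truth lesions.
#' @slot lesionDiameterRange numeric(2), mm.
#' @slot pExtrapulmonary,pWallAttached fractions in [0, 1].
#' @slot nFpIntra,nFpExtra planted false-candidate structures (vessel-like
#'   tubes inside the lungs / blobs in the chest wall) excluded from ground
#'   truth.
#' @slot noiseSd additive Gaussian noise, HU.
#' @slot seed integer RNG seed.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(shape = "integer", spacing = "numeric", nLesions = "integer",
                 lesionDiameterRange = "numeric", pExtrapulmonary = "numeric",
                 pWallAttached = "numeric", nFpIntra = "integer",
                 nFpExtra = "integer", noiseSd = "numeric", seed = "integer"))
setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@lesionDiameterRange[1] < 2 * max(object@spacing))
    msg <- c(msg, "minimum lesion diameter must be >= 2 * max(spacing)")
  if (object@nLesions < 0L) msg <- c(msg, "nLesions must be >= 0")
  if (object@pExtrapulmonary < 0 || object@pExtrapulmonary > 1 ||
      object@pWallAttached < 0 || object@pWallAttached > 1)
    msg <- c(msg, "placement fractions must lie in [0, 1]")
  if (object@pExtrapulmonary + object@pWallAttached > 1)
    msg <- c(msg, "pExtrapulmonary + pWallAttached must be <= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname PhantomSpec-class
#' @param shape,spacing grid geometry.
#' @param nLesions ground-truth lesion count.
#' @param lesionDiameterRange sampled uniformly, mm.
#' @param pExtrapulmonary,pWallAttached location-tag fractions.
#' @param nFpIntra,nFpExtra planted false-candidate structures.
#' @param noiseSd additive Gaussian noise SD, HU.
#' @param seed RNG seed.
#' @export
phantomSpec <- function(shape = c(128, 128, 80), spacing = c(3, 3, 2.5),
                        nLesions = 2, lesionDiameterRange = c(10, 26),
                        pExtrapulmonary = 0, pWallAttached = 0.2,
                        nFpIntra = 1, nFpExtra = 1, noiseSd = 10,
                        seed = 1L) {
  new("PhantomSpec", shape = as.integer(shape), spacing = as.numeric(spacing),
      nLesions = as.integer(nLesions),
      lesionDiameterRange = as.numeric(lesionDiameterRange),
      pExtrapulmonary = pExtrapulmonary, pWallAttached = pWallAttached,
      nFpIntra = as.integer(nFpIntra), nFpExtra = as.integer(nFpExtra),
      noiseSd = noiseSd, seed = as.integer(seed))
}

#' One generated phantom case
#'
#' @slot ct [CTVolume-class].
#' @slot gtLesions ground-truth [InstanceMask-class].
#' @slot lungMask anatomical lung field, [BinaryMask-class].
#' @slot lesionInfo per-lesion metadata: label, center (mm), diameter (mm),
#'   location tag.
#' @slot distractorInfo metadata of planted false-candidate structures.
#' @exportClass PhantomCase
setClass("PhantomCase",
  representation(ct = "CTVolume", gtLesions = "InstanceMask",
                 lungMask = "BinaryMask", lesionInfo = "data.frame",
                 distractorInfo = "data.frame"))

# ---- evaluation containers --------------------------------------------------

#' Lesion match table for one case
#'
#' Overlap graph between ground-truth and predicted instances: a (gt, pred)
#' pair is present iff the voxel intersection is non-empty, with the pair's
#' Dice coefficient and 95th-percentile Hausdorff distance.
#'
#' @slot gtInfo per-gt-lesion data.frame (label, nVoxels, diameterMm).
#' @slot predInfo per-predicted-lesion data.frame (label, nVoxels, overlaps).
#' @slot pairs data.frame (gt, pred, dsc, hd95).
#' @exportClass MatchTable
setClass("MatchTable",
  representation(gtInfo = "data.frame", predInfo = "data.frame",
                 pairs = "data.frame"))

#' Minimum-size (RECIST-style) ground-truth lesion filter
#'
#' Lesions whose maximum in-plane (axial) Feret diameter is below
#' `minDiameterMm` are excluded from the evaluation denominator; the default
#' 10 mm matches the measurable-lesion convention.
#'
#' @slot minDiameterMm numeric, mm.
#' @exportClass SizeFilter
setClass("SizeFilter", representation(minDiameterMm = "numeric"),
         prototype(minDiameterMm = 10))
setValidity("SizeFilter", function(object) {
  if (object@minDiameterMm < 0) "minDiameterMm must be >= 0" else TRUE
})

#' @rdname SizeFilter-class
#' @param minDiameterMm minimum axial diameter in mm (0 disables filtering).
#' @export
sizeFilter <- function(minDiameterMm = 10) {
  new("SizeFilter", minDiameterMm = minDiameterMm)
}

#' Cohort evaluation report
#'
#' @slot detection list(F1, precision, recall).
#' @slot segmentation list(dscImage, dscLesion, hd95Lesion).
#' @slot froc data.frame of (fpPerScan, sensitivity) operating points.
#' @slot volume list(r2, bias, loaLow, loaHigh) in liters.
#' @slot bootstrap data.frame of per-metric resample mean and 95% CI.
#' @slot perCase per-case metric data.frame.
#' @exportClass EvalReport
setClass("EvalReport",
  representation(detection = "list", segmentation = "list",
                 froc = "data.frame", volume = "list",
                 bootstrap = "data.frame", perCase = "data.frame"))
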