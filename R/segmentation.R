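# Stage 2: pluggable binary lesion segmentation on the cropped volume,
# 26-connectivity instance labeling, and padding back to the original grid.
#
# The segmentation network itself is a pluggable backend behind the
# SegmentationBackend interface: any model mapping a CT crop to a
# grid-congruent binary mask can be attached. Two backends ship with the
# package: a fixed HU-threshold backend (exact on noise-free phantoms and
# useful as an oracle in tests) and a trainable multiscale-intensity
# voxelwise neural classifier sized for CPU training on phantom cohorts.

#' Pluggable binary segmentation backend (virtual)
#'
#' Implementations provide [fitBackend()] and [predictMask()];
#' `predictMask` output must be grid-congruent with its input crop.
#' @exportClass SegmentationBackend
setClass("SegmentationBackend", representation("VIRTUAL"))

#' Fixed HU-threshold segmentation backend
#'
#' Marks voxels above `thresholdHu` as lesion. On noise-free phantoms with
#' the package's HU palette (body 0 HU, lesions +20 HU) the default
#' threshold of 10 HU reproduces the rasterized ground truth exactly,
#' making this backend the segmentation oracle for pipeline tests.
#'
#' @slot thresholdHu numeric HU cutoff.
#' @exportClass ThresholdBackend
setClass("ThresholdBackend", contains = "SegmentationBackend",
         representation(thresholdHu = "numeric"),
         prototype(thresholdHu = 10))

#' @rdname ThresholdBackend-class
#' @param thresholdHu HU cutoff above which a voxel is lesion.
#' @export
thresholdBackend <- function(thresholdHu = 10) {
  new("ThresholdBackend", thresholdHu = thresholdHu)
}

#' Trainable multiscale-intensity voxel classifier backend
#'
#' Each voxel is described by its HU value, Gaussian-smoothed values at two
#' physical scales, a center-surround contrast and a local intensity SD;
#' a compact dense neural network maps the feature vector to a lesion
#' probability. Trained with BCE/Adam on voxels sampled from the training
#' crops (all foreground voxels plus a background sample).
#'
#' @slot net trained network weights (empty until fitted).
#' @slot probThreshold Dice-calibrated voxel probability cutoff.
#' @slot featMean,featSd training feature standardization.
#' @slot sigmasMm the two smoothing scales in mm.
#' @slot bgPerFg background voxels sampled per foreground voxel.
#' @slot maxFgPerCase foreground sampling cap per case.
#' @slot config the [TrainConfig-class] used for fitting.
#' @slot curve training curve (per-epoch losses).
#' @exportClass VoxelNetBackend
setClass("VoxelNetBackend", contains = "SegmentationBackend",
  representation(net = "list", sigmasMm = "numeric", bgPerFg = "numeric",
                 maxFgPerCase = "integer", config = "TrainConfig",
                 curve = "data.frame", featMean = "numeric",
                 featSd = "numeric", probThreshold = "numeric"),
  prototype(net = list(), sigmasMm = c(3, 6), bgPerFg = 3,
            maxFgPerCase = 4000L, featMean = numeric(),
            featSd = numeric(), probThreshold = 0.5))

#' @rdname VoxelNetBackend-class
#' @param sigmasMm Gaussian feature scales, mm.
#' @param bgPerFg background:foreground sampling ratio.
#' @param maxFgPerCase per-case cap on sampled foreground voxels.
#' @param config a [TrainConfig-class]; the default uses larger batches and
#'   fewer epochs than the classifier recipe because the sample unit is a
#'   voxel, not a patch.
#' @export
voxelNetBackend <- function(sigmasMm = c(3, 6), bgPerFg = 3,
                            maxFgPerCase = 4000,
                            config = trainConfig(batchSize = 256,
                                                 maxEpochs = 40,
                                                 patience = 10,
                                                 hidden = 16)) {
  new("VoxelNetBackend", sigmasMm = sigmasMm, bgPerFg = bgPerFg,
      maxFgPerCase = as.integer(maxFgPerCase), config = config,
      curve = data.frame())
}

# two display-window normalizations, as a radiologist would read the scan:
# a wide lung window and a narrow soft-tissue window that spreads the small
# lesion-vs-soft-tissue HU contrast over the feature range
.windowHu <- function(arr, lo, hi) pmin(pmax((arr - lo) / (hi - lo), 0), 1)

.voxelFeatures <- function(ct, sigmasMm) {
  sp <- voxelSpacing(ct)
  wide <- .windowHu(ct@data, -1000, 100)
  soft <- .windowHu(ct@data, -100, 60)
  w1 <- .gaussSmooth(wide, sp, sigmasMm[1])
  s1 <- .gaussSmooth(soft, sp, sigmasMm[1])
  s2 <- .gaussSmooth(soft, sp, sigmasMm[2])
  m2 <- .gaussSmooth(soft^2, sp, sigmasMm[1])
  sd1 <- sqrt(pmax(m2 - s1^2, 0))
  # wide-window local SD: large at air/tissue interfaces (lung border,
  # body contour), small inside homogeneous tissue
  mw2 <- .gaussSmooth(wide^2, sp, sigmasMm[1])
  sdw <- sqrt(pmax(mw2 - w1^2, 0))
  # large-scale context: mean density in a ~10 mm neighborhood separates
  # "in the lung" (low), "at the pleural interface" (mid) and "inside the
  # body" (high); combined with the absolute soft-window value this lets
  # the net tell a lesion at the lung border from a partial-volume shell
  wctx <- .gaussSmooth(wide, sp, 10)
  cbind(as.vector(wide), as.vector(soft), as.vector(w1), as.vector(s1),
        as.vector(s2), as.vector(soft - s2), as.vector(sd1),
        as.vector(sdw), as.vector(wctx))
}

#' @describeIn isTrained threshold backends need no training.
#' @export
setMethod("isTrained", "ThresholdBackend", function(x) TRUE)

#' @describeIn isTrained trained once `fitBackend` has populated the net.
#' @export
setMethod("isTrained", "VoxelNetBackend", function(x) length(x@net) > 0)

#' @describeIn trainingCurve per-epoch train/validation loss.
#' @param x a fitted backend.
#' @export
setMethod("trainingCurve", "VoxelNetBackend", function(x) x@curve)

#' @describeIn fitBackend no-op for the threshold backend.
#' @export
setMethod("fitBackend", "ThresholdBackend",
          function(backend, volumes, masks, ...) backend)

#' @describeIn fitBackend sample voxels across cases and fit the dense net.
#' @param seed RNG seed for voxel sampling and optimization.
#' @export
setMethod("fitBackend", "VoxelNetBackend",
  function(backend, volumes, masks, seed = 1L, ...) {
    stopifnot(length(volumes) == length(masks), length(volumes) >= 1)
    Xs <- list(); ys <- list()
    .withSeed(seed, {
      for (i in seq_along(volumes)) {
        .stopIfIncongruent(volumes[[i]], masks[[i]])
        F <- .voxelFeatures(volumes[[i]], backend@sigmasMm)
        fg <- which(masks[[i]]@data != 0)
        bg <- which(masks[[i]]@data == 0)
        if (length(fg) > backend@maxFgPerCase)
          fg <- sample(fg, backend@maxFgPerCase)
        nbg <- min(length(bg),
                   max(1000L, ceiling(backend@bgPerFg * length(fg))))
        # stratified background: uniform draws plus hard negatives from
        # tissue-density voxels and high-variance interfaces (pleural
        # partial-volume shells are rare globally but are exactly what a
        # lesion-intensity classifier confuses)
        third <- ceiling(nbg / 3)
        bgTissue <- bg[F[bg, 2] > 0.3]
        bgIface <- bg[F[bg, 2] > 0.3 & F[bg, 8] > 0.15]
        bgSel <- c(sample(bg, third),
                   if (length(bgTissue)) sample(bgTissue, min(third,
                     length(bgTissue))),
                   if (length(bgIface)) sample(bgIface, min(third,
                     length(bgIface))))
        Xs[[i]] <- F[c(fg, bgSel), , drop = FALSE]
        ys[[i]] <- c(rep(1, length(fg)), rep(0, length(bgSel)))
      }
    })
    X <- do.call(rbind, Xs)
    y <- unlist(ys)
    backend@featMean <- colMeans(X)
    backend@featSd <- pmax(apply(X, 2, stats::sd), 1e-8)
    X <- scale(X, center = backend@featMean, scale = backend@featSd)
    sel <- .withSeed(seed + 7L, sample.int(length(y)))
    nVal <- max(1L, floor(0.2 * length(y)))
    vi <- sel[seq_len(nVal)]
    ti <- sel[-seq_len(nVal)]
    fit <- .dnTrain(X[ti, , drop = FALSE], y[ti], X[vi, , drop = FALSE],
                    y[vi], config = backend@config, seed = seed)
    backend@net <- fit$net
    backend@curve <- fit$curve
    # Calibrate the voxel-probability threshold on full training volumes:
    # training voxels are sampled near-balanced while the true lesion
    # prior is ~1e-4, so the Dice-optimal operating point sits far above
    # 0.5. Maximize mean whole-volume Dice over a log-spaced grid.
    nCal <- min(5L, length(volumes))
    ths <- 1 - 10^seq(-0.3, -6, length.out = 30)
    diceSum <- numeric(length(ths))
    for (i in seq_len(nCal)) {
      p <- .voxelNetProb(backend, volumes[[i]])
      g <- as.vector(masks[[i]]@data != 0)
      ng <- sum(g)
      for (t in seq_along(ths)) {
        pr <- p > ths[t]
        diceSum[t] <- diceSum[t] +
          if (ng + sum(pr) == 0) 1 else 2 * sum(pr & g) / (ng + sum(pr))
      }
    }
    backend@probThreshold <- ths[which.max(diceSum)]
    backend
  })

#' @describeIn predictMask HU thresholding.
#' @export
setMethod("predictMask", "ThresholdBackend", function(backend, ct) {
  BinaryMask(array(as.integer(ct@data > backend@thresholdHu), dim(ct@data)),
             spacing = voxelSpacing(ct), origin = voxelOrigin(ct))
})

# voxel lesion-probability map: dense-net posteriors lightly smoothed at
# the feature scale, which suppresses isolated-voxel noise responses
.voxelNetProb <- function(backend, ct) {
  F <- .voxelFeatures(ct, backend@sigmasMm)
  F <- scale(F, center = backend@featMean, scale = backend@featSd)
  p <- array(.dnPredict(backend@net, F), dim(ct@data))
  as.vector(.gaussSmooth(p, voxelSpacing(ct), backend@sigmasMm[1]))
}

#' @describeIn predictMask smoothed dense-net voxel probabilities above the
#'   Dice-calibrated threshold.
#' @export
setMethod("predictMask", "VoxelNetBackend", function(backend, ct) {
  if (!isTrained(backend)) stop("untrained backend")
  p <- .voxelNetProb(backend, ct)
  BinaryMask(array(as.integer(p > backend@probThreshold), dim(ct@data)),
             spacing = voxelSpacing(ct), origin = voxelOrigin(ct))
})

#' Segment a (cropped) CT volume with a trained backend
#'
#' @param backend a trained [SegmentationBackend-class].
#' @param ctCrop the [CTVolume-class] crop.
#' @return a [BinaryMask-class] on the crop grid.
#' @export
segmentBinary <- function(backend, ctCrop) {
  if (!isTrained(backend)) stop("untrained backend")
  out <- predictMask(backend, ctCrop)
  .stopIfIncongruent(ctCrop, out, "backend output and input crop")
  out
}

#' Label lesion instances by 3-D connected components (26-connectivity)
#'
#' Every 26-connected foreground component receives a distinct label
#' `1..n`, assigned in deterministic column-major scan order of each
#' component's first voxel.
#'
#' @param mask a [BinaryMask-class] (an [InstanceMask-class] is binarized
#'   first, so relabeling an already-labeled mask preserves the partition).
#' @return an [InstanceMask-class].
#' @export
labelInstances <- function(mask) {
  stopifnot(is(mask, "VoxelGrid"))
  lab <- .label26(mask@data)
  attr(lab, "n_components") <- NULL
  InstanceMask(lab, spacing = voxelSpacing(mask), origin = voxelOrigin(mask))
}

#' Extract per-instance lesion candidates
#'
#' One row per predicted instance with voxel count, physical volume,
#' tight bounding box, centroid in physical coordinates and maximum axial
#' (in-plane) Feret diameter.
#'
#' @param pred an [InstanceMask-class].
#' @param ct optional grid-congruent [CTVolume-class] (checked when given).
#' @return a data.frame with one row per candidate.
#' @export
extractCandidates <- function(pred, ct = NULL) {
  stopifnot(is(pred, "InstanceMask"))
  if (!is.null(ct)) .stopIfIncongruent(ct, pred)
  labels <- instanceLabels(pred)
  sp <- voxelSpacing(pred)
  if (length(labels) == 0)
    return(data.frame(label = integer(), nVoxels = integer(),
                      volumeMm3 = numeric(), centroidX = numeric(),
                      centroidY = numeric(), centroidZ = numeric(),
                      loX = integer(), loY = integer(), loZ = integer(),
                      hiX = integer(), hiY = integer(), hiZ = integer(),
                      diameterMm = numeric()))
  voxVol <- prod(sp)
  rows <- lapply(labels, function(k) {
    ijk <- which(pred@data == k, arr.ind = TRUE)
    ctr <- colMeans(.voxelCenters(ijk, sp, voxelOrigin(pred)))
    data.frame(label = k, nVoxels = nrow(ijk),
               volumeMm3 = nrow(ijk) * voxVol,
               centroidX = ctr[1], centroidY = ctr[2], centroidZ = ctr[3],
               loX = min(ijk[, 1]), loY = min(ijk[, 2]), loZ = min(ijk[, 3]),
               hiX = max(ijk[, 1]), hiY = max(ijk[, 2]), hiZ = max(ijk[, 3]),
               diameterMm = .axialDiameterIjk(ijk, sp))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
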