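# Stage 3: cascade false-positive reduction (CFPR). Each predicted
# candidate is assessed by the extrapulmonary classifier (XPC) on a
# coronal patch pair; candidates that survive are validated by the lesion
# validator (LVC) on a 3-D patch pair. Rejected candidates are erased from
# the mask; the cascade only ever removes voxels.

#' Cascade candidate classifier (virtual)
#'
#' Implementations map a [CandidatePatchPair-class] to the probability of
#' class 1 (true lesion) via [predictProb()].
#' @exportClass CandidateClassifier
setClass("CandidateClassifier", representation("VIRTUAL"))

#' Classifier wrapping an arbitrary scoring function
#'
#' Useful for oracle classifiers in tests and for attaching external
#' models: `fn(pair)` must return a probability in [0, 1]. The pair's
#' candidate identity travels in `attr(pair, "context")` when produced by
#' [runCfpr()].
#'
#' @slot fn scoring function.
#' @exportClass FunctionClassifier
setClass("FunctionClassifier", contains = "CandidateClassifier",
         representation(fn = "function"))

#' @rdname FunctionClassifier-class
#' @param fn function(pair) -> probability of class 1.
#' @export
functionClassifier <- function(fn) new("FunctionClassifier", fn = fn)

#' Dense-network patch classifier
#'
#' Average-pools the raw and candidate-mask channels of a patch pair onto
#' a coarse grid and classifies the concatenated descriptor with the
#' package's compact dense network, trained with the standard recipe
#' (BCE, Adam, lr 1e-3, weight decay 1e-4, batch 32, early stopping after
#' 30 epochs without validation-loss improvement, and random
#' translation/flip/zoom/noise augmentation of training patches).
#'
#' @slot poolShape pooled grid shape (length 2 for coronal XPC patches,
#'   length 3 for LVC crops).
#' @slot centerFrac when positive, the central `centerFrac` fraction of
#'   the patch is pooled again on the same grid and appended to the
#'   descriptor — a second, finer scale so small candidates keep shape
#'   information (96 mm crops pool to 12 mm bins at the coarse scale).
#' @slot net trained weights (empty until fitted).
#' @slot curve training curve.
#' @exportClass DenseNetClassifier
setClass("DenseNetClassifier", contains = "CandidateClassifier",
  representation(poolShape = "integer", centerFrac = "numeric",
                 net = "list", curve = "data.frame"),
  prototype(net = list(), curve = data.frame(), centerFrac = 0))

#' @rdname DenseNetClassifier-class
#' @param poolShape pooled descriptor grid.
#' @param centerFrac central-crop fraction for the second descriptor
#'   scale (0 disables; default 0.5 for 3-D patches).
#' @export
denseNetClassifier <- function(poolShape = c(16, 16),
                               centerFrac = if (length(poolShape) == 3)
                                 0.5 else 0) {
  new("DenseNetClassifier", poolShape = as.integer(poolShape),
      centerFrac = centerFrac)
}

#' @describeIn isTrained function classifiers are always usable.
#' @export
setMethod("isTrained", "FunctionClassifier", function(x) TRUE)

#' @describeIn isTrained trained once fitted.
#' @export
setMethod("isTrained", "DenseNetClassifier", function(x) length(x@net) > 0)

#' @describeIn trainingCurve per-epoch train/validation loss.
#' @param x a fitted object.
#' @export
setMethod("trainingCurve", "DenseNetClassifier", function(x) x@curve)

# pooled descriptor: raw, candidate mask, and their product (the intensity
# context under the candidate -- e.g. lung-density support for the XPC);
# optionally repeated on the central fraction of the patch as a second,
# finer scale
# The mask and product channels are renormalized to peak 1 so that small
# candidates remain visible after pooling (a few-voxel candidate would
# otherwise pool to ~1e-3 and the classifier could not even locate it);
# candidate size is carried separately as an explicit scalar.
.poolChannels <- function(raw, mask, d3, p3) {
  pm <- .avg_pool3d(as.numeric(mask), as.integer(d3), as.integer(p3))
  pp <- .avg_pool3d(as.numeric(raw * mask), as.integer(d3), as.integer(p3))
  mx <- max(pm)
  if (mx > 0) { pm <- pm / mx; pp <- pp / mx }
  c(.avg_pool3d(as.numeric(raw), as.integer(d3), as.integer(p3)), pm, pp)
}

# candidate-support scalars: the mean raw intensity under the candidate
# and in a blurred ring around it. The ring mean is the pulmonary-boundary
# context the coronal classifier hypothesizes on: a candidate surrounded
# by aerated lung reads dark, one embedded in the chest wall reads bright,
# at any candidate size.
.supportScalars <- function(r3, m3, d3) {
  nm <- sum(m3)
  if (nm == 0) return(c(0, 0))
  candMean <- sum(r3 * m3) / nm
  # ring computed on a pooled grid for speed; the blurred candidate mask
  # weights the surround
  q3 <- pmin(d3, c(32L, 32L, if (d3[3] > 1) 32L else 1L))
  rp <- array(.avg_pool3d(as.numeric(r3), as.integer(d3), as.integer(q3)), q3)
  mp <- array(.avg_pool3d(as.numeric(m3), as.integer(d3), as.integer(q3)), q3)
  b <- .gaussSmooth(mp, c(1, 1, 1), c(2, 2, if (q3[3] > 1) 2 else 0))
  ring <- b * (1 - mp)
  sw <- sum(ring)
  ringMean <- if (sw > 1e-9) sum(rp * ring) / sw else 0
  c(candMean, ringMean)
}

.poolPair <- function(pair, poolShape, centerFrac = 0) {
  d <- dim(pair@raw)
  nd <- length(d)
  d3 <- if (nd == 2) c(d, 1L) else d
  p3 <- if (length(poolShape) == 2) c(poolShape, 1L) else poolShape
  r3 <- array(pair@raw, d3)
  m3 <- array(pair@mask, d3)
  out <- c(.poolChannels(r3, m3, d3, p3), log1p(sum(m3)),
           .supportScalars(r3, m3, d3))
  if (centerFrac > 0) {
    lo <- pmax(1L, as.integer(floor(d3 * (1 - centerFrac) / 2)) + 1L)
    hi <- pmin(d3, lo + as.integer(ceiling(d3 * centerFrac)) - 1L)
    if (nd == 2) { lo[3] <- 1L; hi[3] <- 1L }
    rc <- r3[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    mc <- m3[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    out <- c(out, .poolChannels(rc, mc, dim(rc), p3))
  }
  out
}

# Patch pairs may be materialized on disk and referenced by path. The raw
# channel is quantized to 16 bits (it is already min-max normalized), the
# mask channel stored as integers; files are written uncompressed so
# cohort-scale patch extraction is I/O-bound, not CPU-bound.
.savePair <- function(pair, path) {
  rawQ <- array(as.integer(round(pair@raw * 65535)), dim(pair@raw))
  mask <- array(as.integer(pair@mask), dim(pair@mask))
  saveRDS(list(rawQ = rawQ, mask = mask, geometry = pair@geometry),
          path, compress = FALSE)
  path
}

.loadPair <- function(x) {
  if (!is.character(x)) return(x)
  obj <- readRDS(x)
  new("CandidatePatchPair", raw = obj$rawQ / 65535,
      mask = obj$mask * 1, geometry = obj$geometry)
}

#' @describeIn predictProb apply the wrapped scoring function.
#' @export
setMethod("predictProb", signature("FunctionClassifier", "ANY"),
  function(classifier, pair) {
    if (is.list(pair))
      return(vapply(pair, function(p) classifier@fn(.loadPair(p)),
                    numeric(1)))
    classifier@fn(.loadPair(pair))
  })

#' @describeIn predictProb pooled-descriptor dense-net probability.
#' @export
setMethod("predictProb", signature("DenseNetClassifier", "ANY"),
  function(classifier, pair) {
    if (!isTrained(classifier)) stop("untrained classifier")
    pairs <- if (is.list(pair)) pair else list(pair)
    X <- do.call(rbind, lapply(pairs, function(p)
      .poolPair(.loadPair(p), classifier@poolShape,
                classifier@centerFrac)))
    p <- .dnPredict(classifier@net, X)
    if (is.list(pair)) p else p[1]
  })

# random translation/flip/zoom/Gaussian-noise augmentation of one patch
.augmentPatch <- function(raw, mask, config) {
  d <- dim(raw)
  nd <- length(d)
  d3 <- if (nd == 2) c(d, 1L) else d
  r3 <- array(raw, d3); m3 <- array(mask, d3)
  # flips
  for (a in seq_len(nd)) {
    if (stats::runif(1) < 0.5) {
      idx <- rep(list(quote(expr = )), 3)
      idx[[a]] <- rev(seq_len(d3[a]))
      r3 <- do.call(`[`, c(list(r3), idx, list(drop = FALSE)))
      m3 <- do.call(`[`, c(list(m3), idx, list(drop = FALSE)))
    }
  }
  # zoom + translation in one resampling pass (unit spacing grid)
  zoom <- 1 + stats::runif(1, -config@maxZoom, config@maxZoom)
  shift <- stats::runif(3, -config@maxShiftFrac, config@maxShiftFrac) *
    (d3 - 1)
  if (nd == 2) shift[3] <- 0
  ctr <- (d3 - 1) / 2
  ospacing <- rep(1 / zoom, 3)
  oorigin <- ctr - ospacing * ctr + shift
  r3 <- array(.resample_grid(as.numeric(r3), as.integer(d3), rep(1, 3),
                             rep(0, 3), as.integer(d3), ospacing, oorigin,
                             0), d3)
  m3 <- array(.resample_grid(as.numeric(m3), as.integer(d3), rep(1, 3),
                             rep(0, 3), as.integer(d3), ospacing, oorigin,
                             0), d3)
  r3 <- r3 + stats::rnorm(length(r3), 0, config@noiseSd)
  r3 <- pmin(pmax(r3, 0), 1)
  m3 <- (m3 >= 0.5) * 1
  if (nd == 2) { dim(r3) <- d; dim(m3) <- d }
  list(raw = r3, mask = m3)
}

#' @describeIn fitClassifier pool (augmented) patch pairs and fit the
#'   dense network with early stopping.
#' @export
setMethod("fitClassifier", "DenseNetClassifier",
  function(classifier, pairs, labels, config = trainConfig(),
           valPairs = NULL, valLabels = NULL, seed = 1L) {
    stopifnot(length(pairs) == length(labels))
    labels <- as.numeric(labels)
    if (length(unique(labels)) < 2L)
      stop("single-class training set: both classes must be present")
    if (is.null(valPairs)) {
      sel <- .withSeed(seed + 13L, {
        i0 <- which(labels == 0); i1 <- which(labels == 1)
        c(sample(i0, max(1L, floor(0.2 * length(i0)))),
          sample(i1, max(1L, floor(0.2 * length(i1)))))
      })
      valPairs <- pairs[sel]
      valLabels <- labels[sel]
      pairs <- pairs[-sel]
      labels <- labels[-sel]
    }
    ps <- classifier@poolShape
    # patches are loaded (from disk when materialized) one at a time, so
    # only pooled descriptors stay resident
    rows <- .withSeed(seed + 29L, {
      lapply(seq_along(pairs), function(i) {
        pr <- .loadPair(pairs[[i]])
        base <- .poolPair(pr, ps, classifier@centerFrac)
        augs <- lapply(seq_len(config@augmentCopies), function(k) {
          a <- .augmentPatch(pr@raw, pr@mask, config)
          ap <- new("CandidatePatchPair", raw = a$raw, mask = a$mask,
                    geometry = pr@geometry)
          .poolPair(ap, ps, classifier@centerFrac)
        })
        do.call(rbind, c(list(base), augs))
      })
    })
    Xtr <- do.call(rbind, rows)
    ytr <- rep(labels, each = 1L + config@augmentCopies)
    Xval <- do.call(rbind, lapply(valPairs, function(p)
      .poolPair(.loadPair(p), ps, classifier@centerFrac)))
    fit <- .dnTrain(Xtr, ytr, Xval, as.numeric(valLabels), config = config,
                    seed = seed)
    classifier@net <- fit$net
    classifier@curve <- fit$curve
    classifier
  })

# ---- patch construction -----------------------------------------------------

.candidateCentroidMm <- function(pred, label) {
  ijk <- which(pred@data == label, arr.ind = TRUE)
  if (nrow(ijk) == 0) stop("label ", label, " absent from mask")
  colMeans(.voxelCenters(ijk, voxelSpacing(pred), voxelOrigin(pred)))
}

#' Build the XPC (coronal) patch pair for one candidate
#'
#' Takes the full coronal plane (constant-y slice) through the candidate's
#' centroid, rounded to the nearest slice; the plane — the whole field of
#' view, since identifying extrapulmonary candidates needs body context —
#' is resampled to the configured patch size at isotropic in-plane
#' resolution. The raw channel is min-max normalized to [0, 1]; the mask
#' channel carries only this candidate's voxels.
#'
#' @param ct the [CTVolume-class] on the original grid.
#' @param pred the [InstanceMask-class] of candidates.
#' @param label candidate instance id.
#' @param cfg a [CascadeConfig-class].
#' @return a [CandidatePatchPair-class] with geometry `"2D-coronal"`.
#' @export
makeXpcPatch <- function(ct, pred, label, cfg = cascadeConfig()) {
  .stopIfIncongruent(ct, pred)
  ctr <- .candidateCentroidMm(pred, label)
  sp <- voxelSpacing(ct)
  org <- voxelOrigin(ct)
  d <- dim(ct@data)
  iy <- min(max(round((ctr[2] - org[2]) / sp[2]) + 1, 1), d[2])
  raw2 <- ct@data[, iy, , drop = FALSE]
  msk2 <- (pred@data[, iy, , drop = FALSE] == label) * 1
  sdims <- as.integer(c(d[1], 1L, d[3]))
  oN <- cfg@xpcSize
  # map output pixel centers across the source voxel-center range
  osp <- c(if (oN[1] > 1) (d[1] - 1) * sp[1] / (oN[1] - 1) else sp[1], sp[2],
           if (oN[2] > 1) (d[3] - 1) * sp[3] / (oN[2] - 1) else sp[3])
  oorg <- c(org[1], org[2] + (iy - 1) * sp[2], org[3])
  fill <- min(ct@data)
  raw <- .resample_grid(as.numeric(raw2), sdims, sp, oorg,
                        as.integer(c(oN[1], 1L, oN[2])), osp, oorg, fill)
  msk <- .resample_grid(as.numeric(msk2), sdims, sp, oorg,
                        as.integer(c(oN[1], 1L, oN[2])), osp, oorg, 0)
  new("CandidatePatchPair",
      raw = matrix(.minMax01(raw), oN[1], oN[2]),
      mask = matrix((msk >= 0.5) * 1, oN[1], oN[2]),
      geometry = "2D-coronal")
}

#' Build the LVC (3-D crop) patch pair for one candidate
#'
#' A cube of physical side `lvcSize * patchSpacingMm` (96 mm by default)
#' centered on the candidate centroid, resampled to isotropic resolution.
#' Regions outside the volume are filled with the volume's minimum HU
#' (air) before the 0-1 normalization.
#'
#' @inheritParams makeXpcPatch
#' @return a [CandidatePatchPair-class] with geometry `"3D-crop"`.
#' @export
makeLvcPatch <- function(ct, pred, label, cfg = cascadeConfig()) {
  .stopIfIncongruent(ct, pred)
  ctr <- .candidateCentroidMm(pred, label)
  sp <- voxelSpacing(ct)
  org <- voxelOrigin(ct)
  d <- dim(ct@data)
  oN <- cfg@lvcSize
  osp <- rep(cfg@patchSpacingMm, 3)
  oorg <- ctr - (oN - 1) * osp / 2
  fill <- min(ct@data)
  raw <- .resample_grid(as.numeric(ct@data), as.integer(d), sp, org,
                        as.integer(oN), osp, oorg, fill)
  msk <- .resample_grid(as.numeric((pred@data == label) * 1), as.integer(d),
                        sp, org, as.integer(oN), osp, oorg, 0)
  new("CandidatePatchPair",
      raw = array(.minMax01(raw), oN),
      mask = array((msk >= 0.5) * 1, oN),
      geometry = "3D-crop")
}

#' One cascade keep/drop decision
#'
#' The extrapulmonary score is `pE = 1 - pXpcLesion` (classifiers output
#' the probability of class 1, "true lesion"). A candidate with
#' `pE >= thrE` is dropped at the XPC stage; otherwise it is kept iff the
#' LVC probability strictly surpasses `thrI`. Sentinel thresholds outside
#' [0, 1] force pass-all (`thrE > 1`, `thrI < 0`) or drop-all behavior.
#'
#' @param pXpcLesion XPC probability of class 1 (true lesion).
#' @param pLvcLesion LVC probability, or `NA` if not evaluated; an error
#'   if the candidate passes the XPC gate without an LVC probability.
#' @param cfg a [CascadeConfig-class].
#' @return list(keep, stage, pE); `stage` names the deciding classifier.
#' @export
cascadeDecide <- function(pXpcLesion, pLvcLesion = NA_real_,
                          cfg = cascadeConfig()) {
  pE <- 1 - pXpcLesion
  if (pE >= cfg@thrE)
    return(list(keep = FALSE, stage = "XPC", pE = pE))
  if (is.na(pLvcLesion))
    stop("candidate passed the XPC gate but no LVC probability is available")
  list(keep = pLvcLesion > cfg@thrI, stage = "LVC", pE = pE)
}

#' Run the cascade false-positive reducer over a predicted mask
#'
#' Every candidate is scored by the XPC (and, when it passes the gate, by
#' the LVC); dropped candidates' voxels are set to 0 and survivors are
#' relabeled `1..m` preserving their relative order. The cascade is
#' removal-only and its result is independent of candidate processing
#' order. Stage toggles support the ablation pipelines: with `useXpc =
#' FALSE` the XPC gate is skipped, with `useLvc = FALSE` candidates
#' passing the XPC gate are kept unconditionally.
#'
#' @param ct [CTVolume-class] on the original grid.
#' @param pred [InstanceMask-class] of candidates.
#' @param xpc,lvc [CandidateClassifier-class] objects (unused stages may be
#'   `NULL` when toggled off).
#' @param cfg a [CascadeConfig-class].
#' @param useXpc,useLvc stage toggles.
#' @return list(mask = filtered [InstanceMask-class], decisions =
#'   per-candidate data.frame of label, pXpc, pE, pLvc, stage, keep,
#'   newLabel).
#' @export
runCfpr <- function(ct, pred, xpc, lvc, cfg = cascadeConfig(),
                    useXpc = TRUE, useLvc = TRUE) {
  .stopIfIncongruent(ct, pred)
  labels <- instanceLabels(pred)
  n <- length(labels)
  dec <- data.frame(label = labels, pXpc = NA_real_, pE = NA_real_,
                    pLvc = NA_real_, stage = NA_character_, keep = TRUE,
                    newLabel = NA_integer_)
  for (r in seq_len(n)) {
    k <- labels[r]
    keep <- TRUE
    stage <- NA_character_
    if (useXpc) {
      xp <- makeXpcPatch(ct, pred, k, cfg)
      attr(xp, "context") <- list(label = k, pred = pred, ct = ct)
      dec$pXpc[r] <- predictProb(xpc, xp)
      dec$pE[r] <- 1 - dec$pXpc[r]
      if (dec$pE[r] >= cfg@thrE) {
        keep <- FALSE
        stage <- "XPC"
      }
    }
    if (keep && useLvc) {
      lp <- makeLvcPatch(ct, pred, k, cfg)
      attr(lp, "context") <- list(label = k, pred = pred, ct = ct)
      dec$pLvc[r] <- predictProb(lvc, lp)
      keep <- dec$pLvc[r] > cfg@thrI
      stage <- "LVC"
    }
    dec$keep[r] <- keep
    dec$stage[r] <- stage
  }
  survivors <- dec$label[dec$keep]
  dec$newLabel[dec$keep] <- seq_along(survivors)
  arr <- pred@data
  remap <- integer(max(c(labels, 0L)) + 1L)
  remap[survivors + 1L] <- seq_along(survivors)
  arr[] <- remap[arr + 1L]
  list(mask = InstanceMask(arr, spacing = voxelSpacing(pred),
                           origin = voxelOrigin(pred)),
       decisions = dec)
}
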