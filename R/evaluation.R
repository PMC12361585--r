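# Multi-lesion evaluation protocol: overlap-based detection (a predicted
# lesion is a true positive iff it overlaps any ground-truth annotation,
# DSC > 0), image- and lesion-level Dice, 95th-percentile Hausdorff
# distance, RECIST-style minimum-diameter filtering of ground-truth
# lesions, FROC analysis, volume agreement (R^2 + Bland-Altman) and
# case-level bootstrap confidence intervals.

.maskArr <- function(x) {
  if (is(x, "VoxelGrid")) x@data != 0 else x != 0
}

#' Dice similarity coefficient between two voxel sets
#'
#' `2|A n B| / (|A| + |B|)`. When both sets are empty the coefficient is 1
#' by convention, flagged via the `"degenerate"` attribute.
#'
#' @param a,b logical/0-1 arrays or [VoxelGrid-class] masks on the same
#'   grid.
#' @return Dice coefficient in [0, 1].
#' @export
dsc <- function(a, b) {
  if (is(a, "VoxelGrid") && is(b, "VoxelGrid")) .stopIfIncongruent(a, b)
  A <- .maskArr(a); B <- .maskArr(b)
  if (!identical(dim(A), dim(B))) stop("grid mismatch")
  na <- sum(A); nb <- sum(B)
  if (na + nb == 0) return(structure(1, degenerate = TRUE))
  2 * sum(A & B) / (na + nb)
}

.surfacePointsMm <- function(arr, spacing) {
  d <- dim(arr)
  surf <- array(.surface6(as.integer(arr != 0), as.integer(d)), d)
  ijk <- which(surf != 0, arr.ind = TRUE)
  .voxelCenters(ijk, spacing, c(0, 0, 0))
}

#' 95th-percentile Hausdorff distance between two masks, in mm
#'
#' The 95th percentile (type-7 quantile) of the pooled directed surface
#' distances in both directions, using anisotropic voxel spacing. Surface
#' voxels are foreground voxels with a 6-neighbor background voxel (or
#' grid edge).
#'
#' @param a,b non-empty masks (arrays or [VoxelGrid-class]) on one grid.
#' @param spacing numeric(3) voxel spacing in mm (taken from `a` when it is
#'   a grid object).
#' @return distance in mm.
#' @export
hd95 <- function(a, b, spacing = NULL) {
  if (is(a, "VoxelGrid")) {
    if (is(b, "VoxelGrid")) .stopIfIncongruent(a, b)
    spacing <- voxelSpacing(a)
  }
  stopifnot(!is.null(spacing))
  A <- .maskArr(a); B <- .maskArr(b)
  if (!identical(dim(A), dim(B))) stop("grid mismatch")
  if (sum(A) == 0 || sum(B) == 0) stop("hd95 undefined for empty masks")
  pa <- .surfacePointsMm(A, spacing)
  pb <- .surfacePointsMm(B, spacing)
  dab <- .directed_min_dists(pa, pb)
  dba <- .directed_min_dists(pb, pa)
  as.numeric(stats::quantile(c(dab, dba), 0.95, type = 7))
}

# axial Feret diameter from 1-based voxel indices (n x 3)
.axialDiameterIjk <- function(ijk, spacing) {
  if (nrow(ijk) == 0) stop("empty voxel set")
  best <- 0
  for (z in unique(ijk[, 3])) {
    pts <- ijk[ijk[, 3] == z, 1:2, drop = FALSE]
    P <- cbind((pts[, 1] - 1) * spacing[1], (pts[, 2] - 1) * spacing[2])
    d <- .max_pairwise_dist2d(P)
    if (d > best) best <- d
  }
  best
}

#' Maximum in-plane (axial) Feret diameter of a lesion, in mm
#'
#' The maximum over constant-z slices of the maximum pairwise distance
#' between foreground voxel centers — the RECIST-style axial diameter used
#' by the measurable-lesion (>= 10 mm) filter. A single voxel has
#' diameter 0.
#'
#' @param lesion non-empty mask (array or [VoxelGrid-class]).
#' @param spacing numeric(3) spacing in mm (from the object when a grid).
#' @return diameter in mm.
#' @export
axialDiameter <- function(lesion, spacing = NULL) {
  if (is(lesion, "VoxelGrid")) spacing <- voxelSpacing(lesion)
  stopifnot(!is.null(spacing))
  A <- .maskArr(lesion)
  ijk <- which(A, arr.ind = TRUE)
  if (nrow(ijk) == 0) stop("empty voxel set")
  .axialDiameterIjk(ijk, spacing)
}

#' Match ground-truth and predicted lesion instances by overlap
#'
#' Builds the overlap graph: a (gt, pred) pair appears iff the voxel
#' intersection is non-empty, with the pair's DSC and Hd-95 computed on
#' the pair's own voxel sets.
#'
#' @param gt,pred grid-congruent [InstanceMask-class] objects.
#' @return a [MatchTable-class].
#' @export
matchLesions <- function(gt, pred) {
  .stopIfIncongruent(gt, pred, "gt and pred masks")
  sp <- voxelSpacing(gt)
  gtLabs <- instanceLabels(gt)
  predLabs <- instanceLabels(pred)
  gtInfo <- if (length(gtLabs) > 0) {
    do.call(rbind, lapply(gtLabs, function(g) {
      ijk <- which(gt@data == g, arr.ind = TRUE)
      data.frame(label = g, nVoxels = nrow(ijk),
                 diameterMm = .axialDiameterIjk(ijk, sp))
    }))
  } else data.frame(label = integer(), nVoxels = integer(),
                    diameterMm = numeric())
  predCounts <- vapply(predLabs, function(p) sum(pred@data == p), integer(1))
  pairs <- data.frame(gt = integer(), pred = integer(), dsc = numeric(),
                      hd95 = numeric())
  if (length(gtLabs) > 0 && length(predLabs) > 0) {
    both <- gt@data > 0 & pred@data > 0
    ov <- table(factor(gt@data[both], levels = gtLabs),
                factor(pred@data[both], levels = predLabs))
    hits <- which(ov > 0, arr.ind = TRUE)
    if (nrow(hits)) {
      pairs <- do.call(rbind, lapply(seq_len(nrow(hits)), function(r) {
        gi <- hits[r, 1]; pi <- hits[r, 2]
        g <- gtLabs[gi]; p <- predLabs[pi]
        inter <- ov[gi, pi]
        d <- 2 * inter / (gtInfo$nVoxels[gi] + predCounts[pi])
        h <- hd95(gt@data == g, pred@data == p, spacing = sp)
        data.frame(gt = as.integer(g), pred = as.integer(p),
                   dsc = as.numeric(d), hd95 = h)
      }))
    }
  }
  predInfo <- data.frame(label = as.integer(predLabs),
                         nVoxels = as.integer(predCounts),
                         overlaps = predLabs %in% pairs$pred)
  if (length(predLabs) == 0)
    predInfo <- data.frame(label = integer(), nVoxels = integer(),
                           overlaps = logical())
  new("MatchTable", gtInfo = gtInfo, predInfo = predInfo, pairs = pairs)
}

# gt labels surviving the size filter for one table
.filteredGt <- function(table, filter) {
  table@gtInfo$label[table@gtInfo$diameterMm >= filter@minDiameterMm]
}

#' Pooled detection metrics over a cohort
#'
#' Micro-averaged over all lesions across cases. Ground-truth lesions
#' below the size filter are excluded from the recall denominator and do
#' not confer true-positive status on predictions. A predicted lesion
#' overlapping at least one (filtered) ground-truth lesion counts once as
#' a true positive, regardless of how many it covers.
#'
#' @param tables list of [MatchTable-class], one per case.
#' @param filter a [SizeFilter-class].
#' @return list(F1, precision, recall, nGt, nPred, tpPred, detectedGt).
#' @export
detectionMetrics <- function(tables, filter = sizeFilter()) {
  nGt <- 0L; nPred <- 0L; tpPred <- 0L; detGt <- 0L
  for (tb in tables) {
    keepG <- .filteredGt(tb, filter)
    nGt <- nGt + length(keepG)
    nPred <- nPred + nrow(tb@predInfo)
    pr <- tb@pairs[tb@pairs$gt %in% keepG, , drop = FALSE]
    tpPred <- tpPred + length(unique(pr$pred))
    detGt <- detGt + length(unique(pr$gt))
  }
  precision <- if (nPred > 0) tpPred / nPred else NA_real_
  recall <- if (nGt > 0) detGt / nGt else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(F1 = f1, precision = precision, recall = recall, nGt = nGt,
       nPred = nPred, tpPred = tpPred, detectedGt = detGt)
}

#' Image- and lesion-level segmentation metrics over a cohort
#'
#' Image-level DSC is the macro-average over cases of the whole-mask DSC
#' (union of predicted lesions vs union of filtered ground-truth lesions).
#' Lesion-level DSC averages, over filtered ground-truth lesions, the
#' highest pair DSC among matches (0 when unmatched). Lesion-level Hd-95
#' averages the lowest pair Hd-95 over filtered, matched ground-truth
#' lesions only (the two optima may come from different predictions).
#'
#' @param cases list of `list(gt = , pred = )` [InstanceMask-class] pairs.
#' @param tables matching [MatchTable-class] list (recomputed when NULL).
#' @param filter a [SizeFilter-class].
#' @return list(dscImage, dscLesion, hd95Lesion, nHd95, degenerateCases).
#' @export
segmentationMetrics <- function(cases, tables = NULL, filter = sizeFilter()) {
  if (is.null(tables))
    tables <- lapply(cases, function(cs) matchLesions(cs$gt, cs$pred))
  stopifnot(length(cases) == length(tables))
  imgD <- numeric(length(cases))
  degen <- 0L
  lesD <- numeric(0)
  lesH <- numeric(0)
  for (i in seq_along(cases)) {
    tb <- tables[[i]]
    keepG <- .filteredGt(tb, filter)
    gArr <- cases[[i]]$gt@data %in% keepG
    dim(gArr) <- dim(cases[[i]]$gt@data)
    d <- dsc(gArr, cases[[i]]$pred@data != 0)
    if (isTRUE(attr(d, "degenerate"))) degen <- degen + 1L
    imgD[i] <- as.numeric(d)
    for (g in keepG) {
      pr <- tb@pairs[tb@pairs$gt == g, , drop = FALSE]
      lesD <- c(lesD, if (nrow(pr)) max(pr$dsc) else 0)
      if (nrow(pr)) lesH <- c(lesH, min(pr$hd95))
    }
  }
  list(dscImage = mean(imgD),
       dscLesion = if (length(lesD)) mean(lesD) else NA_real_,
       hd95Lesion = if (length(lesH)) mean(lesH) else NA_real_,
       nHd95 = length(lesH), degenerateCases = degen)
}

#' FROC operating points: lesion sensitivity vs mean false positives/scan
#'
#' Sweeps a keep-threshold over per-candidate scores (for the full
#' pipeline, the lesion-validator probabilities; pass-through scores give
#' the single no-filter operating point). At each threshold, candidates
#' with score >= threshold survive; the point records the mean number of
#' surviving non-overlapping predictions per case and the pooled
#' sensitivity over filtered ground-truth lesions.
#'
#' @param tables list of [MatchTable-class] per case.
#' @param scores list of numeric vectors, one score per predicted label in
#'   the corresponding case (named or positional by label).
#' @param filter a [SizeFilter-class].
#' @return data.frame of (threshold, fpPerScan, sensitivity), sorted by
#'   fpPerScan.
#' @export
frocCurve <- function(tables, scores, filter = sizeFilter()) {
  stopifnot(length(tables) == length(scores))
  if (!length(unlist(scores))) stop("no candidate scores provided")
  allS <- sort(unique(unlist(scores)))
  thresholds <- c(allS, max(allS) + 1)  # +1 drops everything
  nGt <- 0L
  perGt <- list()
  for (i in seq_along(tables)) {
    keepG <- .filteredGt(tables[[i]], filter)
    nGt <- nGt + length(keepG)
    perGt[[i]] <- keepG
  }
  pts <- lapply(thresholds, function(th) {
    fp <- 0L; det <- 0L
    for (i in seq_along(tables)) {
      tb <- tables[[i]]
      s <- scores[[i]]
      surv <- tb@predInfo$label[s >= th]
      pr <- tb@pairs[tb@pairs$pred %in% surv & tb@pairs$gt %in% perGt[[i]],
                     , drop = FALSE]
      det <- det + length(unique(pr$gt))
      fp <- fp + sum(!surv %in% tb@pairs$pred[tb@pairs$gt %in% perGt[[i]]])
    }
    data.frame(threshold = th, fpPerScan = fp / length(tables),
               sensitivity = if (nGt > 0) det / nGt else NA_real_)
  })
  out <- do.call(rbind, pts)
  out[order(out$fpPerScan, out$sensitivity), ]
}

#' Volume agreement: R^2 and Bland-Altman bias / limits of agreement
#'
#' Volumes are per-case total lesion volumes in liters. R^2 comes from the
#' least-squares linear fit of predicted on ground-truth volume; the
#' Bland-Altman bias is `mean(pred - gt)` with limits of agreement
#' `bias +/- 1.96 * sd(pred - gt)`.
#'
#' @param predVolumesL,gtVolumesL numeric vectors, liters, length >= 3.
#' @return list(r2, bias, loaLow, loaHigh, n).
#' @export
volumeAgreement <- function(predVolumesL, gtVolumesL) {
  stopifnot(length(predVolumesL) == length(gtVolumesL))
  if (length(predVolumesL) < 3) stop("need at least 3 volume pairs")
  if (stats::var(gtVolumesL) == 0) stop("zero variance in ground-truth volumes")
  fit <- stats::lm(predVolumesL ~ gtVolumesL)
  # summary.lm warns on exact fits (identical volumes); R^2 = 1 is the
  # intended answer there
  r2 <- suppressWarnings(summary(fit)$r.squared)
  diffs <- predVolumesL - gtVolumesL
  bias <- mean(diffs)
  s <- stats::sd(diffs)
  list(r2 = r2, bias = bias, loaLow = bias - 1.96 * s,
       loaHigh = bias + 1.96 * s, n = length(diffs))
}

#' Total lesion volume of a mask, in liters
#' @param mask an [InstanceMask-class] or [BinaryMask-class].
#' @return volume in liters (voxel count x voxel volume x 1e-6).
#' @export
lesionVolumeL <- function(mask) {
  sum(mask@data != 0) * prod(voxelSpacing(mask)) * 1e-6
}

#' Case-resampling bootstrap mean and percentile confidence interval
#'
#' Resamples cases (CT scans) with replacement — the resampling unit for
#' every metric, since lesions are not independent within a scan — and
#' recomputes the metric per resample. Resamples on which the metric is
#' undefined (errors or NA) are skipped and counted; a warning is issued
#' when more than 1% are skipped.
#'
#' @param metricFn function(cases) -> scalar; `cases` is a list or vector.
#' @param cases list (or vector) of per-case inputs.
#' @param nResamples number of bootstrap resamples.
#' @param seed RNG seed (deterministic CIs under a fixed seed).
#' @param conf confidence level.
#' @return list(mean, lo, hi, nSkipped).
#' @export
bootstrapCi <- function(metricFn, cases, nResamples = 1000, seed = 1L,
                        conf = 0.95) {
  n <- if (is.list(cases)) length(cases) else length(cases)
  stopifnot(n >= 1)
  vals <- .withSeed(seed, {
    vapply(seq_len(nResamples), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      res <- tryCatch(metricFn(if (is.list(cases)) cases[idx] else
        cases[idx]), error = function(e) NA_real_)
      if (length(res) != 1) NA_real_ else as.numeric(res)
    }, numeric(1))
  })
  skipped <- sum(is.na(vals))
  if (skipped > 0.01 * nResamples)
    warning(sprintf("metric undefined on %d of %d resamples", skipped,
                    nResamples))
  ok <- vals[!is.na(vals)]
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(ok, c(alpha, 1 - alpha), names = FALSE)
  list(mean = mean(ok), lo = qs[1], hi = qs[2], nSkipped = skipped)
}
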