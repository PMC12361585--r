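# Candidate-dataset construction, stratified 5-fold assignment, classifier
# training and cascade threshold tuning.
#
# Candidates come from running the bounding-box + segmentation pipeline on
# training cases: each predicted instance becomes a record labeled 1 when
# it overlaps any ground-truth lesion (max pairwise DSC > 0) and 0
# otherwise, with a location tag from its lung-mask overlap fraction. The
# lesion validator (LVC) trains on all records; the extrapulmonary
# classifier (XPC) trains on the subset of extrapulmonary non-lesions plus
# all true lesions, mirroring how the two classifiers' tasks differ.

#' Labeled candidate dataset with patch pairs
#'
#' @slot records data.frame: caseId, label, class (0/1), tag, maxDsc,
#'   lungFrac.
#' @slot xpc,lvc lists of [CandidatePatchPair-class] parallel to records.
#' @exportClass CandidateDataset
setClass("CandidateDataset",
  representation(records = "data.frame", xpc = "list", lvc = "list"))

setMethod("show", "CandidateDataset", function(object) {
  cat("CandidateDataset: ", nrow(object@records), " candidates (",
      sum(object@records$class == 1), " lesion / ",
      sum(object@records$class == 0), " non-lesion)\n", sep = "")
})

#' @rdname CandidateDataset-class
#' @param ds a [CandidateDataset-class].
#' @export
candidateRecords <- function(ds) ds@records

#' Build the labeled candidate dataset from per-case pipeline predictions
#'
#' One record per predicted candidate. `class` is 1 iff the candidate's
#' maximum DSC against any ground-truth lesion is > 0; the location tag is
#' `"extrapulmonary"` (no lung-mask overlap), `"intrapulmonary"` (fully
#' inside the lung mask) or `"partial"`.
#'
#' @param cases list of per-case lists with elements `ct`
#'   ([CTVolume-class]), `gt` ([InstanceMask-class]), `pred`
#'   ([InstanceMask-class] from the segmentation stage) and `lung`
#'   ([BinaryMask-class]); an optional `id` names the case.
#' @param cfg a [CascadeConfig-class] for patch geometry.
#' @param makePatches build the XPC/LVC patch pairs (set `FALSE` for
#'   record-only bookkeeping).
#' @param patchDir when non-NULL, patches are materialized to this
#'   directory as RDS files and referenced by path (full-resolution 3-D
#'   patches are large, so cohort-scale training should materialize).
#' @return a [CandidateDataset-class].
#' @export
buildCandidateDataset <- function(cases, cfg = cascadeConfig(),
                                  makePatches = TRUE, patchDir = NULL) {
  if (!is.null(patchDir) && !dir.exists(patchDir))
    dir.create(patchDir, recursive = TRUE)
  rows <- list(); xs <- list(); ls <- list()
  for (ci in seq_along(cases)) {
    cs <- cases[[ci]]
    id <- if (!is.null(cs$id)) cs$id else ci
    .stopIfIncongruent(cs$ct, cs$pred)
    .stopIfIncongruent(cs$ct, cs$gt)
    .stopIfIncongruent(cs$ct, cs$lung)
    for (k in instanceLabels(cs$pred)) {
      cand <- cs$pred@data == k
      nv <- sum(cand)
      maxDsc <- 0
      gtHit <- unique(cs$gt@data[cand])
      gtHit <- gtHit[gtHit > 0]
      for (g in gtHit) {
        d <- 2 * sum(cand & cs$gt@data == g) /
          (nv + sum(cs$gt@data == g))
        if (d > maxDsc) maxDsc <- d
      }
      lungFrac <- sum(cs$lung@data[cand] != 0) / nv
      tag <- if (lungFrac == 0) "extrapulmonary" else
        if (lungFrac >= 1) "intrapulmonary" else "partial"
      rows[[length(rows) + 1L]] <- data.frame(
        caseId = id, label = k, class = as.integer(maxDsc > 0), tag = tag,
        maxDsc = maxDsc, lungFrac = lungFrac, stringsAsFactors = FALSE)
      if (makePatches) {
        xp <- makeXpcPatch(cs$ct, cs$pred, k, cfg)
        lp <- makeLvcPatch(cs$ct, cs$pred, k, cfg)
        if (is.null(patchDir)) {
          xs[[length(xs) + 1L]] <- xp
          ls[[length(ls) + 1L]] <- lp
        } else {
          fx <- file.path(patchDir, sprintf("xpc_%s_%03d.rds", id, k))
          fl <- file.path(patchDir, sprintf("lvc_%s_%03d.rds", id, k))
          .savePair(xp, fx); .savePair(lp, fl)
          xs[[length(xs) + 1L]] <- fx
          ls[[length(ls) + 1L]] <- fl
        }
      }
    }
  }
  records <- if (length(rows)) do.call(rbind, rows) else
    data.frame(caseId = character(), label = integer(), class = integer(),
               tag = character(), maxDsc = numeric(), lungFrac = numeric())
  new("CandidateDataset", records = records, xpc = xs, lvc = ls)
}

#' Subset a candidate dataset for XPC training
#'
#' Keeps non-lesion records tagged extrapulmonary together with all
#' true-lesion records (which lie entirely or partially within the lungs):
#' the extrapulmonary-filtering training set.
#'
#' @param ds a [CandidateDataset-class].
#' @return the filtered [CandidateDataset-class].
#' @export
subsetForXpc <- function(ds) {
  keep <- (ds@records$class == 0 & ds@records$tag == "extrapulmonary") |
    ds@records$class == 1
  new("CandidateDataset",
      records = ds@records[keep, , drop = FALSE],
      xpc = if (length(ds@xpc)) ds@xpc[keep] else list(),
      lvc = if (length(ds@lvc)) ds@lvc[keep] else list())
}

#' Bin z-spacing into resolution strata
#'
#' Bins of <= 1 mm, 1-3 mm and > 3 mm reconstruction spacing by default.
#'
#' @param zSpacingMm numeric vector of z spacings.
#' @param breaks internal bin edges in mm.
#' @return factor of bins.
#' @export
zResolutionBin <- function(zSpacingMm, breaks = c(1, 3)) {
  cut(zSpacingMm, c(-Inf, breaks, Inf),
      labels = c(paste0("<=", breaks[1], "mm"),
                 paste0(breaks[1], "-", breaks[2], "mm"),
                 paste0(">", breaks[2], "mm")))
}

#' Stratified k-fold case assignment
#'
#' Cases are shuffled within each stratum and dealt round-robin to folds,
#' so per-stratum fold counts differ by at most 1. Deterministic under
#' `seed`. Candidate records inherit their case's fold.
#'
#' @param caseIds vector of case identifiers.
#' @param strata stratum key per case (e.g.
#'   `interaction(source, zResolutionBin(sz))`); a single stratum when
#'   NULL.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return data.frame(caseId, fold) with folds in `0..k-1`.
#' @export
assignFolds <- function(caseIds, strata = NULL, k = 5, seed = 1L) {
  n <- length(caseIds)
  if (n < k) stop("fewer cases than folds")
  if (is.null(strata)) strata <- rep(1L, n)
  stopifnot(length(strata) == n)
  fold <- integer(n)
  k <- as.integer(k)
  .withSeed(seed, {
    offset <- 0L
    for (s in unique(strata)) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- as.integer((offset + seq_along(idx) - 1L) %% k)
      offset <- offset + length(idx)
    }
  })
  data.frame(caseId = caseIds, fold = as.integer(fold))
}

#' Fold lookup for candidate records
#' @param records candidate records data.frame with a `caseId` column.
#' @param folds output of [assignFolds()].
#' @return integer fold per record.
#' @export
recordFolds <- function(records, folds) {
  folds$fold[match(records$caseId, folds$caseId)]
}

#' Train one cascade classifier on the training folds of a dataset
#'
#' Trains on candidates whose parent case lies outside `foldIdx` and uses
#' the held fold for early stopping (validation-fold loss).
#'
#' @param ds a [CandidateDataset-class] with patches.
#' @param folds output of [assignFolds()].
#' @param foldIdx held-out fold index.
#' @param type `"xpc"` (coronal patches; the dataset should already be the
#'   [subsetForXpc()] subset) or `"lvc"` (3-D patches).
#' @param classifier untrained classifier; default pools to 8x8 (xpc; the
#'   coarse plane view plus the support scalars carry the
#'   extrapulmonary signal, and fewer nuisance dimensions generalize
#'   better from small candidate sets) or 8x8x8 with a central second
#'   scale (lvc).
#' @param config a [TrainConfig-class]; the XPC default uses a wider
#'   hidden layer and more augmentation copies, again because its
#'   training subset is the smallest.
#' @param seed RNG seed.
#' @return the trained classifier.
#' @export
trainFoldClassifier <- function(ds, folds, foldIdx, type = c("xpc", "lvc"),
                               classifier = NULL, config = NULL,
                               seed = 1L) {
  type <- match.arg(type)
  if (is.null(classifier))
    classifier <- denseNetClassifier(
      if (type == "xpc") c(8L, 8L) else c(8L, 8L, 8L))
  if (is.null(config))
    config <- if (type == "xpc")
      trainConfig(hidden = 24, augmentCopies = 3) else trainConfig()
  pairs <- if (type == "xpc") ds@xpc else ds@lvc
  if (!length(pairs)) stop("dataset has no patches")
  rf <- recordFolds(ds@records, folds)
  tr <- which(rf != foldIdx)
  va <- which(rf == foldIdx)
  if (length(unique(ds@records$class[tr])) < 2L)
    stop("single-class training set")
  fitClassifier(classifier, pairs[tr], ds@records$class[tr],
                config = config, valPairs = pairs[va],
                valLabels = ds@records$class[va], seed = seed)
}

#' Select the classifier with the highest validation AUROC
#'
#' @param classifiers list of trained [CandidateClassifier-class].
#' @param pairs validation patch pairs.
#' @param labels validation 0/1 labels (both classes required).
#' @return list(classifier, auroc, aurocs).
#' @export
selectBestClassifier <- function(classifiers, pairs, labels) {
  if (length(unique(labels)) < 2L)
    stop("validation predictions must cover both classes")
  aurocs <- vapply(classifiers, function(cl)
    .auroc(predictProb(cl, pairs), labels), numeric(1))
  best <- which.max(aurocs)
  list(classifier = classifiers[[best]], auroc = aurocs[best],
       aurocs = aurocs)
}

#' Tune the cascade thresholds on validation cases
#'
#' Exhaustive grid search over `(thrE, thrI)` in `{0, step, ..., 1}^2`.
#' The objective is image-level mean DSC after the cascade, subject to
#' pooled lesion sensitivity within `delta` of the best sensitivity any
#' grid point achieves; ties are broken by higher sensitivity, then lower
#' `thrI`. Per-candidate probabilities are computed once per case, so the
#' grid sweep itself is cheap.
#'
#' @param valCases list of per-case lists with `ct`, `gt`, `pred` (the
#'   un-filtered segmentation instances).
#' @param xpc,lvc trained classifiers.
#' @param cfg a [CascadeConfig-class] (patch geometry; thresholds ignored).
#' @param step grid step.
#' @param delta sensitivity-preservation tolerance.
#' @param filter [SizeFilter-class] applied to ground-truth lesions.
#' @return list(thrE, thrI, dscImage, sensitivity, grid) where `grid`
#'   holds every evaluated point.
#' @export
tuneThresholds <- function(valCases, xpc, lvc, cfg = cascadeConfig(),
                           step = 0.01, delta = 0.01,
                           filter = sizeFilter()) {
  grid <- seq(0, 1, by = step)
  if (!length(grid)) stop("empty threshold grid")
  # cache per-candidate probabilities and overlap bookkeeping
  cache <- lapply(valCases, function(cs) {
    labs <- instanceLabels(cs$pred)
    n <- length(labs)
    tb <- matchLesions(cs$gt, cs$pred)
    keepG <- .filteredGt(tb, filter)
    gtUnion <- sum(cs$gt@data %in% keepG)
    pXpc <- rep(NA_real_, n); pLvc <- rep(NA_real_, n)
    nVox <- integer(n); ovGt <- integer(n)
    for (r in seq_len(n)) {
      k <- labs[r]
      xp <- makeXpcPatch(cs$ct, cs$pred, k, cfg)
      lp <- makeLvcPatch(cs$ct, cs$pred, k, cfg)
      ctx <- list(label = k, pred = cs$pred, ct = cs$ct)
      attr(xp, "context") <- ctx
      attr(lp, "context") <- ctx
      pXpc[r] <- predictProb(xpc, xp)
      pLvc[r] <- predictProb(lvc, lp)
      cand <- cs$pred@data == k
      nVox[r] <- sum(cand)
      ovGt[r] <- sum(cand & array(cs$gt@data %in% keepG, dim(cand)))
    }
    detBy <- lapply(keepG, function(g)
      tb@pairs$pred[tb@pairs$gt == g])
    list(labs = labs, pE = 1 - pXpc, pLvc = pLvc, nVox = nVox, ovGt = ovGt,
         gtUnion = gtUnion, detBy = detBy)
  })
  nGtTotal <- sum(vapply(cache, function(c) length(c$detBy), numeric(1)))
  evalPoint <- function(thrE, thrI) {
    dscs <- numeric(length(cache))
    det <- 0L
    for (i in seq_along(cache)) {
      cc <- cache[[i]]
      surv <- which(!(cc$pE >= thrE) & cc$pLvc > thrI)
      inter <- sum(cc$ovGt[surv])
      tot <- sum(cc$nVox[surv]) + cc$gtUnion
      dscs[i] <- if (tot == 0) 1 else 2 * inter / tot
      survLabs <- cc$labs[surv]
      det <- det + sum(vapply(cc$detBy, function(p) any(p %in% survLabs),
                              logical(1)))
    }
    # vacuous sensitivity (no filtered gt lesions) counts as preserved
    list(dsc = mean(dscs), dscs = dscs,
         sens = if (nGtTotal > 0) det / nGtTotal else 1)
  }
  pts <- expand.grid(thrE = grid, thrI = grid)
  evals <- lapply(seq_len(nrow(pts)),
                  function(r) evalPoint(pts$thrE[r], pts$thrI[r]))
  pts$dscImage <- vapply(evals, `[[`, numeric(1), "dsc")
  pts$sensitivity <- vapply(evals, `[[`, numeric(1), "sens")
  bestSens <- max(pts$sensitivity, na.rm = TRUE)
  feasible <- which(pts$sensitivity >= bestSens - delta)
  if (!length(feasible)) {
    warning("no feasible grid point; returning pass-through sentinels")
    return(list(thrE = 1.01, thrI = -0.01, dscImage = NA_real_,
                sensitivity = NA_real_, grid = pts))
  }
  # one-standard-error rule: a handful of validation cases cannot
  # distinguish near-optimal operating points, and the exact optimizer
  # tends to ride the validation score extremes (an aggressive thr_e that
  # barely spares every validation lesion generalizes poorly). Among
  # feasible points whose mean DSC is within one standard error of the
  # feasible optimum, prefer the most conservative cascade: highest
  # sensitivity, then highest thr_e (least aggressive XPC gate), then
  # lowest thr_i.
  bestIdx <- feasible[which.max(pts$dscImage[feasible])]
  bestDscs <- evals[[bestIdx]]$dscs
  se <- if (length(bestDscs) > 1)
    stats::sd(bestDscs) / sqrt(length(bestDscs)) else 0
  near <- feasible[pts$dscImage[feasible] >=
                     pts$dscImage[bestIdx] - se]
  f <- pts[near, ]
  ord <- order(-f$sensitivity, -f$thrE, -f$dscImage, f$thrI)
  pick <- f[ord[1], ]
  list(thrE = pick$thrE, thrI = pick$thrI, dscImage = pick$dscImage,
       sensitivity = pick$sensitivity, grid = pts)
}

#' Select best per-fold classifiers and tune the cascade thresholds
#'
#' Convenience wrapper: picks the XPC and LVC with the highest validation
#' AUROC from per-fold candidates, then grid-tunes `(thrE, thrI)` on the
#' validation cases.
#'
#' @param xpcClassifiers,lvcClassifiers lists of trained classifiers.
#' @param xpcVal,lvcVal lists with elements `pairs` and `labels` used for
#'   AUROC-based selection.
#' @param valCases threshold-tuning cases (see [tuneThresholds()]).
#' @param cfg patch-geometry [CascadeConfig-class].
#' @param step,delta,filter passed to [tuneThresholds()].
#' @return list(xpc, lvc, thrE, thrI, xpcAuroc, lvcAuroc, tuning).
#' @export
selectBestAndTuneThresholds <- function(xpcClassifiers, lvcClassifiers,
                                        xpcVal, lvcVal, valCases,
                                        cfg = cascadeConfig(), step = 0.01,
                                        delta = 0.01, filter = sizeFilter()) {
  bx <- selectBestClassifier(xpcClassifiers, xpcVal$pairs, xpcVal$labels)
  bl <- selectBestClassifier(lvcClassifiers, lvcVal$pairs, lvcVal$labels)
  tuning <- tuneThresholds(valCases, bx$classifier, bl$classifier, cfg,
                           step = step, delta = delta, filter = filter)
  list(xpc = bx$classifier, lvc = bl$classifier, thrE = tuning$thrE,
       thrI = tuning$thrI, xpcAuroc = bx$auroc, lvcAuroc = bl$auroc,
       tuning = tuning)
}
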