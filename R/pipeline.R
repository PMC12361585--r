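# End-to-end orchestration of the three stages, the ablation switchboard
# (LLS / LLSB / LLSB_XPC / LLSB_LVC / LLSB_CFPR) and cohort-level runs
# with evaluation.

#' Pipeline configuration
#'
#' Stage toggles map onto the five named ablations: `LLS` (segmentation
#' only), `LLSB` (+ thoracic bounding box), `LLSB_XPC`, `LLSB_LVC` and
#' `LLSB_CFPR` (both cascade classifiers); see [ablationConfig()].
#'
#' @slot useBbox,useXpc,useLvc stage toggles.
#' @slot bbox a [BboxConfig-class].
#' @slot cascade a [CascadeConfig-class].
#' @slot backend a [SegmentationBackend-class].
#' @slot xpc,lvc [CandidateClassifier-class] or `NULL`.
#' @slot lungMasker function([CTVolume-class]) -> [BinaryMask-class].
#' @slot seed integer.
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(useBbox = "logical", useXpc = "logical",
                 useLvc = "logical", bbox = "BboxConfig",
                 cascade = "CascadeConfig", backend = "ANY", xpc = "ANY",
                 lvc = "ANY", lungMasker = "function", seed = "integer"))
setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (object@useXpc && !is(object@xpc, "CandidateClassifier"))
    msg <- c(msg, "useXpc requires an XPC classifier")
  if (object@useLvc && !is(object@lvc, "CandidateClassifier"))
    msg <- c(msg, "useLvc requires an LVC classifier")
  if (!is(object@backend, "SegmentationBackend"))
    msg <- c(msg, "backend must be a SegmentationBackend")
  if (length(msg)) msg else TRUE
})

#' @rdname PipelineConfig-class
#' @param backend a trained [SegmentationBackend-class].
#' @param useBbox,useXpc,useLvc stage toggles.
#' @param bbox,cascade stage configurations.
#' @param xpc,lvc trained classifiers (required when toggled on).
#' @param lungMasker lung-mask provider; default [referenceLungMasker()].
#' @param seed seed recorded in provenance and used for any stochastic
#'   backend.
#' @export
pipelineConfig <- function(backend, useBbox = TRUE, useXpc = TRUE,
                           useLvc = TRUE, bbox = bboxConfig(),
                           cascade = cascadeConfig(), xpc = NULL,
                           lvc = NULL, lungMasker = referenceLungMasker,
                           seed = 1L) {
  new("PipelineConfig", useBbox = useBbox, useXpc = useXpc, useLvc = useLvc,
      bbox = bbox, cascade = cascade, backend = backend, xpc = xpc,
      lvc = lvc, lungMasker = lungMasker, seed = as.integer(seed))
}

#' Named ablation configurations
#'
#' @param name one of `"LLS"`, `"LLSB"`, `"LLSB_XPC"`, `"LLSB_LVC"`,
#'   `"LLSB_CFPR"`.
#' @param backend,xpc,lvc,... passed to [pipelineConfig()].
#' @return a [PipelineConfig-class].
#' @export
ablationConfig <- function(name = c("LLSB_CFPR", "LLS", "LLSB", "LLSB_XPC",
                                    "LLSB_LVC"),
                           backend, xpc = NULL, lvc = NULL, ...) {
  name <- match.arg(name)
  toggles <- switch(name,
    LLS = c(FALSE, FALSE, FALSE),
    LLSB = c(TRUE, FALSE, FALSE),
    LLSB_XPC = c(TRUE, TRUE, FALSE),
    LLSB_LVC = c(TRUE, FALSE, TRUE),
    LLSB_CFPR = c(TRUE, TRUE, TRUE))
  pipelineConfig(backend, useBbox = toggles[1], useXpc = toggles[2],
                 useLvc = toggles[3],
                 xpc = if (toggles[2]) xpc else NULL,
                 lvc = if (toggles[3]) lvc else NULL, ...)
}

# 32-bit FNV-1a over the serialized object, for provenance config hashes
.hashObject <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run the full pipeline on one CT volume
#'
#' Stages are applied per the configuration's toggles: lung mask +
#' thoracic bounding box with minimum-size fallback, binary segmentation
#' on the crop, 26-connectivity instance labeling, padding back to the
#' original grid, and cascade false-positive reduction. The provenance
#' record logs the crop box, candidate counts before/after the cascade,
#' per-candidate decisions, the seed and a configuration hash.
#'
#' @param ct a [CTVolume-class].
#' @param cfg a [PipelineConfig-class].
#' @param lungMask optional precomputed [BinaryMask-class] (otherwise the
#'   configured lung masker runs).
#' @return list(mask = [InstanceMask-class] on the original grid,
#'   provenance = list).
#' @export
runPipeline <- function(ct, cfg, lungMask = NULL) {
  validObject(cfg)
  prov <- list(seed = cfg@seed, configHash = .hashObject(
    list(cfg@useBbox, cfg@useXpc, cfg@useLvc, cfg@bbox@minExtentMm,
         cfg@cascade@thrE, cfg@cascade@thrI, class(cfg@backend))))
  if (cfg@useBbox) {
    lm <- if (!is.null(lungMask)) lungMask else cfg@lungMasker(ct)
    .stopIfIncongruent(ct, lm, "volume and lung mask")
    rawBox <- lungBbox(lm)
    box <- applyMinimumFallback(rawBox, ct, cfg@bbox)
    prov$rawBox <- if (is.null(rawBox)) NULL else
      list(lo = rawBox@lo, hi = rawBox@hi)
  } else {
    box <- fullGridBox(ct)
  }
  prov$box <- list(lo = box@lo, hi = box@hi)
  crop <- cropToBox(ct, box)
  record <- cropRecordOf(box, ct)
  bin <- .withSeed(cfg@seed, segmentBinary(cfg@backend, crop))
  inst <- labelInstances(bin)
  pred <- padToOriginal(inst, record)
  prov$nCandidatesBefore <- nInstances(pred)
  if (cfg@useXpc || cfg@useLvc) {
    res <- runCfpr(ct, pred, cfg@xpc, cfg@lvc, cfg@cascade,
                   useXpc = cfg@useXpc, useLvc = cfg@useLvc)
    pred <- res$mask
    prov$decisions <- res$decisions
  }
  prov$nCandidatesAfter <- nInstances(pred)
  list(mask = pred, provenance = prov)
}

#' Run the pipeline over a cohort and (optionally) evaluate it
#'
#' Per-case failures are isolated and reported in `failures`, never fatal
#' to the cohort. When ground truth is present an [EvalReport-class] is
#' produced.
#'
#' @param cases list of [PhantomCase-class] objects, or of lists with
#'   elements `ct` (required), and optional `gt`, `lung`, `id`.
#' @param cfg a [PipelineConfig-class].
#' @param filter [SizeFilter-class] for the evaluation.
#' @param bootstrapResamples bootstrap resamples for the report CIs (0
#'   disables the bootstrap).
#' @param seed evaluation bootstrap seed.
#' @return list(results, report, failures).
#' @export
runCohort <- function(cases, cfg, filter = sizeFilter(),
                      bootstrapResamples = 1000, seed = 1L) {
  norm <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    if (is(cs, "PhantomCase"))
      list(ct = cs@ct, gt = cs@gtLesions, lung = cs@lungMask, id = i)
    else c(cs, list(id = if (!is.null(cs$id)) cs$id else i))
  })
  results <- vector("list", length(norm))
  failures <- data.frame(id = character(), error = character())
  for (i in seq_along(norm)) {
    results[[i]] <- tryCatch(
      runPipeline(norm[[i]]$ct, cfg, lungMask = norm[[i]]$lung),
      error = function(e) {
        failures <<- rbind(failures, data.frame(
          id = as.character(norm[[i]]$id), error = conditionMessage(e)))
        NULL
      })
  }
  ok <- which(!vapply(results, is.null, logical(1)))
  withGt <- ok[vapply(norm[ok], function(cs) !is.null(cs$gt), logical(1))]
  report <- NULL
  if (length(withGt) > 0) {
    evalCases <- lapply(withGt, function(i)
      list(gt = norm[[i]]$gt, pred = results[[i]]$mask,
           decisions = results[[i]]$provenance$decisions))
    report <- buildEvalReport(evalCases, filter = filter,
                              nResamples = bootstrapResamples, seed = seed)
  }
  list(results = results, report = report, failures = failures)
}

#' Assemble the cohort evaluation report
#'
#' Computes pooled detection metrics, image-/lesion-level segmentation
#' metrics, FROC operating points (from the cascade's lesion-validator
#' probabilities when available, else pass-through scores), per-case
#' total-lesion-volume agreement and case-resampling bootstrap CIs.
#'
#' @param cases list of lists with `gt` and `pred` [InstanceMask-class]
#'   objects, optionally `decisions` (from [runCfpr()]) or `scores`.
#' @param filter a [SizeFilter-class].
#' @param nResamples bootstrap resamples (0 disables).
#' @param seed bootstrap seed.
#' @return an [EvalReport-class].
#' @export
buildEvalReport <- function(cases, filter = sizeFilter(),
                            nResamples = 1000, seed = 1L) {
  tables <- lapply(cases, function(cs) matchLesions(cs$gt, cs$pred))
  det <- detectionMetrics(tables, filter)
  seg <- segmentationMetrics(cases, tables, filter)
  # FROC scores: surviving candidates' LVC probability when present
  scores <- lapply(seq_along(cases), function(i) {
    n <- nrow(tables[[i]]@predInfo)
    dcs <- cases[[i]]$decisions
    if (!is.null(cases[[i]]$scores)) cases[[i]]$scores
    else if (!is.null(dcs)) {
      s <- dcs$pLvc[dcs$keep]
      s[is.na(s)] <- 1
      s
    } else rep(1, n)
  })
  froc <- if (length(unlist(scores)))
    frocCurve(tables, scores, filter) else
    data.frame(threshold = numeric(), fpPerScan = numeric(),
               sensitivity = numeric())
  predV <- vapply(cases, function(cs) lesionVolumeL(cs$pred), numeric(1))
  gtV <- vapply(cases, function(cs) lesionVolumeL(cs$gt), numeric(1))
  vol <- if (length(cases) >= 3 && stats::var(gtV) > 0)
    volumeAgreement(predV, gtV) else list()

  # per-case summaries reused by the bootstrap
  perCase <- do.call(rbind, lapply(seq_along(cases), function(i) {
    tb <- tables[[i]]
    keepG <- .filteredGt(tb, filter)
    pr <- tb@pairs[tb@pairs$gt %in% keepG, , drop = FALSE]
    gArr <- cases[[i]]$gt@data %in% keepG
    dim(gArr) <- dim(cases[[i]]$gt@data)
    data.frame(id = i, nGt = length(keepG), nPred = nrow(tb@predInfo),
               tpPred = length(unique(pr$pred)),
               detectedGt = length(unique(pr$gt)),
               fp = nrow(tb@predInfo) - length(unique(pr$pred)),
               dscImage = as.numeric(dsc(gArr, cases[[i]]$pred@data != 0)),
               predVolumeL = predV[i], gtVolumeL = gtV[i])
  }))
  boot <- data.frame(metric = character(), mean = numeric(),
                     lo = numeric(), hi = numeric())
  if (nResamples > 0) {
    rows <- split(perCase, seq_len(nrow(perCase)))
    fns <- list(
      F1 = function(cs) {
        s <- do.call(rbind, cs)
        p <- sum(s$tpPred) / sum(s$nPred)
        r <- sum(s$detectedGt) / sum(s$nGt)
        if (!is.finite(p) || !is.finite(r) || p + r == 0) return(NA_real_)
        2 * p * r / (p + r)
      },
      precision = function(cs) {
        s <- do.call(rbind, cs); sum(s$tpPred) / sum(s$nPred)
      },
      recall = function(cs) {
        s <- do.call(rbind, cs); sum(s$detectedGt) / sum(s$nGt)
      },
      dscImage = function(cs) mean(vapply(cs, function(x) x$dscImage,
                                          numeric(1))),
      fpPerScan = function(cs) mean(vapply(cs, function(x) x$fp,
                                           numeric(1))))
    for (nm in names(fns)) {
      ci <- suppressWarnings(
        bootstrapCi(fns[[nm]], rows, nResamples = nResamples, seed = seed))
      boot <- rbind(boot, data.frame(metric = nm, mean = ci$mean,
                                     lo = ci$lo, hi = ci$hi))
    }
  }
  new("EvalReport",
      detection = det,
      segmentation = seg,
      froc = froc,
      volume = vol,
      bootstrap = boot,
      perCase = perCase)
}
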