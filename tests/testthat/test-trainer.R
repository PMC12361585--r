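# Candidate dataset construction, fold assignment, classifier training and
# threshold tuning.

# a hand-built case: lung box, one gt lesion inside it, three predicted
# candidates with known labels and location tags
.toyTrainingCase <- function() {
  sp <- c(2, 2, 2)
  shp <- c(30, 30, 12)
  lung <- array(0L, shp); lung[8:22, 8:22, 3:10] <- 1L
  gt <- array(0L, shp); gt[10:14, 10:14, 5:7] <- 1L
  pred <- array(0L, shp)
  pred[10:14, 10:14, 5:7] <- 1L   # equals the gt lesion: label 1, intra
  pred[2:4, 2:4, 5:6] <- 2L       # outside the lung: label 0, extra
  pred[20:24, 20:24, 5:6] <- 3L   # straddles the lung edge, no gt: partial
  list(ct = CTVolume(array(0, shp), sp), gt = InstanceMask(gt, sp),
       pred = InstanceMask(pred, sp), lung = BinaryMask(lung, sp), id = "t1")
}

test_that("candidate records carry overlap labels and location tags", {
  ds <- buildCandidateDataset(list(.toyTrainingCase()), makePatches = FALSE)
  rec <- candidateRecords(ds)
  expect_identical(nrow(rec), 3L)
  expect_identical(rec$class, c(1L, 0L, 0L))
  expect_identical(rec$tag, c("intrapulmonary", "extrapulmonary", "partial"))
  expect_equal(rec$maxDsc[1], 1)
  expect_equal(rec$maxDsc[2:3], c(0, 0))
  # deterministic: rebuilding gives identical records
  ds2 <- buildCandidateDataset(list(.toyTrainingCase()), makePatches = FALSE)
  expect_identical(rec, candidateRecords(ds2))
})

test_that("the XPC subset keeps extrapulmonary negatives and all positives", {
  rec <- data.frame(
    caseId = 1, label = 1:6, class = c(0L, 0L, 0L, 1L, 1L, 1L),
    tag = c("extrapulmonary", "intrapulmonary", "partial",
            "extrapulmonary", "partial", "intrapulmonary"),
    maxDsc = c(0, 0, 0, .5, .6, .7), lungFrac = c(0, 1, .5, 0, .5, 1))
  ds <- new("CandidateDataset", records = rec, xpc = as.list(1:6),
            lvc = as.list(1:6))
  out <- candidateRecords(subsetForXpc(ds))
  # label-0 intrapulmonary/partial excluded; label-1 partial included
  expect_identical(out$label, c(1L, 4L, 5L, 6L))
})

test_that("fold assignment is stratified, balanced and inherited", {
  f <- assignFolds(1:10, k = 5, seed = 2)
  expect_identical(sort(unique(f$fold)), 0:4)
  expect_true(all(table(f$fold) == 2))
  # two strata of 5: one case per stratum per fold
  strata <- rep(c("a", "b"), each = 5)
  f2 <- assignFolds(1:10, strata, k = 5, seed = 3)
  tab <- table(f2$fold, strata)
  expect_true(all(tab == 1))
  # determinism
  expect_identical(f2, assignFolds(1:10, strata, k = 5, seed = 3))
  expect_error(assignFolds(1:3, k = 5), "fewer cases than folds")
  # records inherit their case fold
  rec <- data.frame(caseId = c(3, 3, 7, 9))
  expect_identical(recordFolds(rec, f),
                   f$fold[match(c(3, 3, 7, 9), f$caseId)])
})

test_that("z-resolution bins split thin/standard/thick reconstructions", {
  b <- zResolutionBin(c(0.5, 1.0, 2.5, 3.0, 4.5))
  expect_identical(as.integer(b), c(1L, 1L, 2L, 2L, 3L))
})

# synthetic separable patch pairs: lesions are bright blobs under the mask,
# non-lesions empty raw signal
.separablePairs <- function(n, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      lesion <- i %% 2 == 0
      raw <- matrix(stats::runif(32 * 32, 0, 0.1), 32, 32)
      mask <- matrix(0, 32, 32)
      mask[12:20, 12:20] <- 1
      if (lesion) raw[12:20, 12:20] <- raw[12:20, 12:20] + 0.8
      new("CandidatePatchPair", raw = pmin(raw, 1), mask = mask,
          geometry = "2D-coronal")
    })
  })
}

test_that("the dense-net classifier separates separable patches", {
  pairs <- .separablePairs(80, seed = 6)
  labels <- as.integer(seq_len(80) %% 2 == 0)
  clf <- fitClassifier(denseNetClassifier(c(8L, 8L)), pairs, labels,
                       config = trainConfig(maxEpochs = 120, patience = 30),
                       seed = 2)
  expect_true(isTrained(clf))
  held <- .separablePairs(40, seed = 99)
  heldLabels <- as.integer(seq_len(40) %% 2 == 0)
  p <- predictProb(clf, held)
  expect_true(all(p >= 0 & p <= 1))
  auc <- pROC::auc(pROC::roc(heldLabels, p, quiet = TRUE,
                             direction = "<", levels = c(0, 1)))
  expect_gte(as.numeric(auc), 0.95)
  # the loss decreases over the first epochs
  curve <- trainingCurve(clf)
  expect_lt(curve$trainLoss[min(5, nrow(curve))], curve$trainLoss[1])
})

test_that("early stopping halts after `patience` stagnant epochs", {
  pairs <- .separablePairs(40, seed = 7)
  labels <- as.integer(seq_len(40) %% 2 == 0)
  # lr = 0 freezes the weights, so no epoch improves on the first
  clf <- fitClassifier(denseNetClassifier(c(8L, 8L)), pairs, labels,
                       config = trainConfig(lr = 0, patience = 3,
                                            maxEpochs = 100,
                                            augmentCopies = 0), seed = 2)
  expect_identical(nrow(trainingCurve(clf)), 4L)  # 1 best + 3 stagnant
})

test_that("training refuses a single-class set", {
  pairs <- .separablePairs(10, seed = 8)
  expect_error(fitClassifier(denseNetClassifier(c(8L, 8L)), pairs,
                             rep(1L, 10)), "single-class|both classes")
})

test_that("threshold tuning with oracle classifiers removes planted FPs", {
  valCases <- lapply(1:2, function(s) {
    cs <- generatePhantom(tinySpec(seed = 400 + s, nLesions = 2,
                                   nFpIntra = 1, nFpExtra = 1, noiseSd = 0))
    pred <- labelInstances(predictMask(thresholdBackend(10), phantomCt(cs)))
    list(ct = phantomCt(cs), gt = phantomGt(cs), pred = pred,
         lung = phantomLung(cs))
  })
  # oracles close over per-case truth via the patch context
  gtLookup <- lapply(valCases, `[[`, "gt")
  lungLookup <- lapply(valCases, `[[`, "lung")
  caseOf <- function(ctx) {
    for (i in seq_along(valCases))
      if (identical(dim(voxelData(valCases[[i]]$pred)),
                    dim(voxelData(ctx$pred))) &&
          identical(voxelData(valCases[[i]]$pred), voxelData(ctx$pred)))
        return(i)
    stop("unknown case")
  }
  xpc <- functionClassifier(function(pair) {
    ctx <- attr(pair, "context"); i <- caseOf(ctx)
    cand <- voxelData(ctx$pred) == ctx$label
    if (sum(cand & (voxelData(lungLookup[[i]]) != 0)) > 0) 1 else 0
  })
  lvc <- functionClassifier(function(pair) {
    ctx <- attr(pair, "context"); i <- caseOf(ctx)
    cand <- voxelData(ctx$pred) == ctx$label
    if (sum(cand & (voxelData(gtLookup[[i]]) != 0)) > 0) 1 else 0
  })
  tuned <- tuneThresholds(valCases, xpc, lvc, step = 0.25, delta = 0.01,
                          filter = sizeFilter(0))
  expect_equal(tuned$sensitivity, 1)
  expect_equal(tuned$dscImage, 1)  # survivors equal the gt voxel sets
  expect_true(tuned$thrE >= 0 && tuned$thrE <= 1)
  # vacuous constraint returns the unconstrained DSC maximizer
  tunedFree <- tuneThresholds(valCases, xpc, lvc, step = 0.25, delta = 1,
                              filter = sizeFilter(0))
  expect_equal(tunedFree$dscImage, max(tunedFree$grid$dscImage))
  # grid accounting: step 0.5 evaluates at most 9 points
  t9 <- tuneThresholds(valCases[1], xpc, lvc, step = 0.5, delta = 1,
                       filter = sizeFilter(0))
  expect_identical(nrow(t9$grid), 9L)
})

test_that("classifier selection picks the highest validation AUROC", {
  pairs <- .separablePairs(40, seed = 11)
  labels <- as.integer(seq_len(40) %% 2 == 0)
  good <- functionClassifier(function(p) mean(p@raw[p@mask == 1]))
  bad <- functionClassifier(function(p) 0.5)
  coin <- functionClassifier(function(p) 1 - mean(p@raw[p@mask == 1]))
  sel <- selectBestClassifier(list(bad, good, coin), pairs, labels)
  expect_identical(sel$classifier@fn, good@fn)
  expect_gte(sel$auroc, 0.99)
  expect_error(selectBestClassifier(list(good), pairs, rep(1, 40)),
               "both classes")
})
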