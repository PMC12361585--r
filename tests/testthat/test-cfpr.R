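# Cascade false-positive reduction: patch construction, the two-threshold
# decision rule, and removal-only filtering.

# small volume with two labeled blobs, spacing 1 mm
.toyCtPred <- function() {
  arr <- array(0, c(40, 50, 30))
  ct <- CTVolume(arr, spacing = c(1, 1, 1))
  pm <- array(0L, c(40, 50, 30))
  pm[18:22, 38:42, 12:16] <- 1L
  pm[5:6, 10, 25] <- 2L
  list(ct = ct, pred = InstanceMask(pm, spacing = c(1, 1, 1)))
}

test_that("XPC patch selects the centroid coronal slice at fixed size", {
  tp <- .toyCtPred()
  # mark plane y = 40 (the label-1 centroid slice) with a bright band
  arr <- voxelData(tp$ct)
  arr[, 40, ] <- 200
  arr[1, 40, 1] <- 0  # keep the plane non-constant so min-max is defined
  ct <- CTVolume(arr, spacing = c(1, 1, 1))
  pair <- makeXpcPatch(ct, tp$pred, 1)
  expect_identical(dim(pair@raw), c(128L, 128L))
  expect_identical(dim(pair@mask), c(128L, 128L))
  expect_identical(pair@geometry, "2D-coronal")
  # the bright marked plane was picked: raw is (near) constant 1
  expect_gt(mean(pair@raw), 0.95)
  # mask channel carries only candidate 1
  expect_gt(sum(pair@mask), 0)
  pair2 <- makeXpcPatch(ct, tp$pred, 2)
  expect_lt(mean(pair2@raw), 0.05)  # slice y=10 is constant -> mapped to 0
  expect_error(makeXpcPatch(ct, tp$pred, 9), "absent")
})

test_that("single-voxel candidates pick their own slice", {
  arr <- array(0, c(20, 60, 20))
  pm <- array(0L, dim(arr))
  pm[10, 41, 10] <- 1L   # 1-based index 41 -> centroid y = 40 mm
  arr[, 41, ] <- 100
  arr[1, 41, 1] <- 0
  ct <- CTVolume(arr, spacing = c(1, 1, 1))
  pair <- makeXpcPatch(ct, InstanceMask(pm, spacing = c(1, 1, 1)), 1)
  expect_gt(mean(pair@raw), 0.95)
})

test_that("constant volumes give constant (zero) normalized patches", {
  arr <- array(37, c(20, 20, 20))
  pm <- array(0L, dim(arr)); pm[10, 10, 10] <- 1L
  ct <- CTVolume(arr, spacing = c(2, 2, 2))
  pred <- InstanceMask(pm, spacing = c(2, 2, 2))
  expect_true(all(makeXpcPatch(ct, pred, 1)@raw == 0))
  expect_true(all(makeLvcPatch(ct, pred, 1)@raw == 0))
})

test_that("LVC patch is a 96 mm cube resampled to 1 mm isotropic", {
  tp <- .toyCtPred()
  withr::with_seed(2, {
    arr <- array(stats::rnorm(prod(dim(voxelData(tp$ct))), -200, 150),
                 dim(voxelData(tp$ct)))
  })
  ct <- CTVolume(arr, spacing = c(1, 1, 1))
  pair <- makeLvcPatch(ct, tp$pred, 1)
  expect_identical(dim(pair@raw), c(96L, 96L, 96L))
  expect_true(all(pair@raw >= 0 & pair@raw <= 1))
  expect_true(all(pair@mask %in% c(0, 1)))
  # candidate near the volume corner: still 96^3, out-of-volume filled
  pair2 <- makeLvcPatch(ct, tp$pred, 2)
  expect_identical(dim(pair2@raw), c(96L, 96L, 96L))
  # most of the cube lies outside the 40 x 50 x 30 volume -> fill value,
  # which is the volume minimum and hence 0 after normalization
  expect_gt(mean(pair2@raw == 0), 0.5)
})

test_that("a 20 mm sphere keeps its volume through 1 mm resampling", {
  # sphere of radius 10 mm rasterized at 2 mm spacing
  shp <- c(40, 40, 40)
  ctr <- c(39, 39, 39)  # mm, voxel centers at (i-1)*2
  ijk <- as.matrix(expand.grid(1:40, 1:40, 1:40))
  mm <- sweep(ijk - 1, 2, c(2, 2, 2), `*`)
  inside <- rowSums(sweep(mm, 2, ctr, `-`)^2) <= 100
  pm <- array(0L, shp); pm[ijk[inside, , drop = FALSE]] <- 1L
  ct <- CTVolume(array(0, shp), spacing = c(2, 2, 2))
  pred <- InstanceMask(pm, spacing = c(2, 2, 2))
  pair <- makeLvcPatch(ct, pred, 1)
  vol <- sum(pair@mask)  # 1 mm^3 voxels
  expect_lt(abs(vol - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.15)
})

test_that("cascade decisions match the independent truth table", {
  for (thrE in c(0, 0.5, 1)) for (thrI in c(0, 0.5, 1)) {
    cfg <- cascadeConfig(thrE = thrE, thrI = thrI)
    for (pE in c(0, 0.25, 0.5, 0.75, 1)) for (pL in c(0, 0.25, 0.5, 0.75, 1)) {
      got <- cascadeDecide(1 - pE, pL, cfg)
      ref <- oracleCascade(pE, pL, thrE, thrI)
      expect_identical(got$keep, ref == "keep")
      if (!got$keep)
        expect_identical(got$stage, sub("drop", "", ref))
    }
  }
  # certain extrapulmonary candidates drop at the XPC for any thrE <= 1
  for (thrE in c(0, 0.3, 1)) {
    d <- cascadeDecide(0, 0.9, cascadeConfig(thrE = thrE, thrI = 0.1))
    expect_false(d$keep)
    expect_identical(d$stage, "XPC")
  }
  # passing the XPC gate without an LVC probability is an error
  expect_error(cascadeDecide(0.9, NA, cascadeConfig(thrE = 0.5, thrI = 0.5)),
               "LVC probability")
})

test_that("sentinel thresholds keep every candidate and reproduce the input", {
  cs <- generatePhantom(tinySpec(seed = 33, nLesions = 2, nFpIntra = 1,
                                 nFpExtra = 1, noiseSd = 0))
  ct <- phantomCt(cs)
  pred <- labelInstances(predictMask(thresholdBackend(10), ct))
  res <- runCfpr(ct, pred, oracleXpc(phantomLung(cs)),
                 oracleLvc(phantomGt(cs)), passThroughCascade())
  expect_identical(voxelData(res$mask), voxelData(pred))
  expect_true(all(res$decisions$keep))
})

test_that("oracle cascade keeps exactly the true lesions", {
  cs <- generatePhantom(tinySpec(seed = 34, nLesions = 2, nFpIntra = 1,
                                 nFpExtra = 1, noiseSd = 0))
  ct <- phantomCt(cs)
  pred <- labelInstances(predictMask(thresholdBackend(10), ct))
  expect_identical(nInstances(pred), 4L)  # 2 lesions + 2 distractors
  res <- runCfpr(ct, pred, oracleXpc(phantomLung(cs)),
                 oracleLvc(phantomGt(cs)),
                 cascadeConfig(thrE = 0.5, thrI = 0.5))
  expect_identical(nInstances(res$mask), 2L)
  expect_identical(voxelData(res$mask) != 0, voxelData(phantomGt(cs)) != 0)
  # stages: the extrapulmonary distractor drops at XPC, the vessel at LVC
  dropped <- res$decisions[!res$decisions$keep, ]
  expect_setequal(dropped$stage, c("XPC", "LVC"))
})

test_that("the cascade is removal-only and order-invariant", {
  cs <- generatePhantom(tinySpec(seed = 35, nLesions = 2, nFpIntra = 1,
                                 nFpExtra = 1, noiseSd = 0))
  ct <- phantomCt(cs)
  pred <- labelInstances(predictMask(thresholdBackend(10), ct))
  # deterministic pseudo-random classifier, a function of content only
  contentScore <- function(pair) {
    ctx <- attr(pair, "context")
    n <- sum(voxelData(ctx$pred) == ctx$label)
    (n * 2654435761) %% 97 / 96
  }
  clf <- functionClassifier(contentScore)
  for (s in 1:20) {
    cfg <- withr::with_seed(s, cascadeConfig(thrE = stats::runif(1),
                                             thrI = stats::runif(1)))
    res <- runCfpr(ct, pred, clf, clf, cfg)
    # removal-only: output foreground is a subset, voxel sets bit-identical
    out <- voxelData(res$mask)
    expect_true(all(out == 0 | voxelData(pred) != 0))
    for (r in which(res$decisions$keep)) {
      k <- res$decisions$label[r]
      expect_identical(out == res$decisions$newLabel[r],
                       voxelData(pred) == k)
    }
    # order invariance: permute candidate labels, survivors' voxels equal
    perm <- withr::with_seed(s + 100, sample(nInstances(pred)))
    arr <- voxelData(pred)
    arr[arr > 0] <- perm[arr[arr > 0]]
    predP <- InstanceMask(arr, voxelSpacing(pred), voxelOrigin(pred))
    resP <- runCfpr(ct, predP, clf, clf, cfg)
    expect_identical(voxelData(res$mask) != 0, voxelData(resP$mask) != 0)
  }
})

test_that("survivor sets shrink monotonically in the thresholds", {
  cs <- generatePhantom(tinySpec(seed = 36, nLesions = 2, nFpIntra = 1,
                                 nFpExtra = 1, noiseSd = 0))
  ct <- phantomCt(cs)
  pred <- labelInstances(predictMask(thresholdBackend(10), ct))
  clf <- functionClassifier(function(pair) {
    ctx <- attr(pair, "context")
    (sum(voxelData(ctx$pred) == ctx$label) %% 11) / 10
  })
  survivors <- function(thrE, thrI) {
    d <- runCfpr(ct, pred, clf, clf,
                 cascadeConfig(thrE = thrE, thrI = thrI))$decisions
    d$label[d$keep]
  }
  base <- survivors(0.7, 0.3)
  expect_true(all(survivors(0.7, 0.6) %in% base))  # raising thrI
  expect_true(all(survivors(0.4, 0.3) %in% base))  # lowering thrE
})
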