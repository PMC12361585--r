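# Evaluation protocol: Dice, Hd-95, diameters, overlap matching, pooled
# metrics, FROC, volume agreement and the case bootstrap.

test_that("dsc matches set arithmetic and handles degenerate input", {
  a <- array(0L, c(4, 4, 4)); a[1:2, 1, 1] <- 1L
  b <- array(0L, c(4, 4, 4)); b[2:3, 1, 1] <- 1L
  expect_equal(dsc(a, a), 1)
  expect_equal(dsc(a, b), 0.5)  # |a|=2, |b|=2, intersection 1
  z <- array(0L, c(4, 4, 4))
  d0 <- dsc(z, z)
  expect_equal(as.numeric(d0), 1)
  expect_true(isTRUE(attr(d0, "degenerate")))
  withr::with_seed(31, {
    for (i in 1:20) {
      x <- randomMask(c(8, 8, 8), 0.3)
      y <- randomMask(c(8, 8, 8), 0.3)
      expect_equal(dsc(x, y), oracleDsc(x, y))
      expect_equal(dsc(x, y), dsc(y, x))  # symmetry
    }
  })
})

test_that("hd95 agrees with the brute-force oracle", {
  a <- array(0L, c(10, 10, 10)); a[3:5, 3:5, 3:5] <- 1L
  expect_equal(hd95(a, a, spacing = c(1, 2, 3)), 0)
  # two single voxels 3 mm apart along z
  p <- array(0L, c(5, 5, 5)); p[2, 2, 1] <- 1L
  q <- array(0L, c(5, 5, 5)); q[2, 2, 2] <- 1L
  expect_equal(hd95(p, q, spacing = c(1, 1, 3)), 3)
  expect_error(hd95(p, array(0L, c(5, 5, 5)), spacing = c(1, 1, 1)),
               "empty")
  withr::with_seed(17, {
    for (i in 1:10) {
      x <- randomMask(c(7, 7, 7), 0.25)
      y <- randomMask(c(7, 7, 7), 0.25)
      if (sum(x) == 0 || sum(y) == 0) next
      sp <- stats::runif(3, 0.5, 4)
      expect_equal(hd95(x, y, spacing = sp), oracleHd95(x, y, sp),
                   tolerance = 1e-9)
      expect_equal(hd95(x, y, spacing = sp), hd95(y, x, spacing = sp))
    }
  })
})

test_that("axial diameter is the in-plane Feret diameter", {
  a <- array(0L, c(20, 20, 4)); a[5, 5, 2] <- 1L
  expect_equal(axialDiameter(a, c(1, 1, 1)), 0)
  b <- array(0L, c(20, 20, 4)); b[4:14, 7, 2] <- 1L  # 11-voxel line
  expect_equal(axialDiameter(b, c(1, 1, 1)), 10)
  # digitized 20 mm sphere at 1 mm isotropic
  ijk <- as.matrix(expand.grid(1:24, 1:24, 1:24))
  inside <- rowSums(sweep(ijk, 2, c(12, 12, 12), `-`)^2) <= 100
  s <- array(0L, c(24, 24, 24)); s[ijk[inside, , drop = FALSE]] <- 1L
  d <- axialDiameter(s, c(1, 1, 1))
  expect_gte(d, 18); expect_lte(d, 21)
})

test_that("matchLesions builds the overlap graph", {
  sp <- c(1, 1, 1)
  gt <- array(0L, c(12, 12, 4)); gt[2:4, 2:4, 2] <- 1L; gt[8:10, 8:10, 2] <- 2L
  # disjoint prediction
  pd <- array(0L, c(12, 12, 4)); pd[6, 6, 3] <- 1L
  tb <- matchLesions(InstanceMask(gt, sp), InstanceMask(pd, sp))
  expect_identical(nrow(tb@pairs), 0L)
  expect_false(any(tb@predInfo$overlaps))
  # perfect prediction: k one-to-one matches at DSC 1
  tb2 <- matchLesions(InstanceMask(gt, sp), InstanceMask(gt, sp))
  expect_identical(nrow(tb2@pairs), 2L)
  expect_true(all(tb2@pairs$dsc == 1))
  expect_true(all(tb2@pairs$hd95 == 0))
  # one prediction spanning two gt lesions: both matched, pred counted once
  span <- array(0L, c(12, 12, 4)); span[2:10, 2:10, 2] <- 1L
  tb3 <- matchLesions(InstanceMask(gt, sp), InstanceMask(span, sp))
  expect_identical(sort(tb3@pairs$gt), c(1L, 2L))
  det <- detectionMetrics(list(tb3), sizeFilter(0))
  expect_equal(det$recall, 1)       # both gt detected
  expect_equal(det$precision, 1)    # the one pred is a TP once
})

test_that("pooled detection metrics match hand arithmetic", {
  sp <- c(2, 2, 2)
  gt <- array(0L, c(20, 20, 6))
  gt[2:5, 2:5, 2:3] <- 1L; gt[8:11, 8:11, 2:3] <- 2L; gt[14:17, 14:17, 2:3] <- 3L
  pd <- array(0L, c(20, 20, 6))
  pd[2:5, 2:5, 2:3] <- 1L       # hits gt 1
  pd[8:11, 8:11, 2:3] <- 2L     # hits gt 2
  pd[2:5, 14:17, 5] <- 3L       # FP
  pd[14:17, 2:5, 5] <- 4L       # FP
  tb <- matchLesions(InstanceMask(gt, sp), InstanceMask(pd, sp))
  det <- detectionMetrics(list(tb), sizeFilter(0))
  expect_equal(det$recall, 2 / 3)
  expect_equal(det$precision, 1 / 2)
  expect_equal(det$F1, 2 * (1 / 2 * 2 / 3) / (1 / 2 + 2 / 3))
})

test_that("the size filter excludes small gt from recall and TP status", {
  sp <- c(1, 1, 1)
  gt <- array(0L, c(30, 30, 4))
  gt[2:16, 2:16, 2] <- 1L        # ~15 mm wide: measurable
  gt[25:27, 25:27, 2] <- 2L      # ~2 mm: below the 10 mm filter
  pd <- array(0L, c(30, 30, 4))
  pd[2:16, 2:16, 2] <- 1L
  pd[25:27, 25:27, 2] <- 2L      # overlaps only the sub-filter lesion
  tb <- matchLesions(InstanceMask(gt, sp), InstanceMask(pd, sp))
  det <- detectionMetrics(list(tb), sizeFilter(10))
  expect_equal(det$nGt, 1L)
  expect_equal(det$recall, 1)          # the measurable lesion is found
  expect_equal(det$precision, 1 / 2)   # small-only overlap confers no TP
  # with the filter disabled both count
  det0 <- detectionMetrics(list(tb), sizeFilter(0))
  expect_equal(det0$precision, 1)
  expect_equal(det0$recall, 1)
})

test_that("segmentation metrics follow the best-match rules", {
  sp <- c(1, 1, 1)
  gt <- array(0L, c(24, 24, 4)); gt[2:13, 2:13, 2] <- 1L
  # two predictions overlapping the same gt with different quality
  pd <- array(0L, c(24, 24, 4))
  pd[2:13, 2:9, 2] <- 1L    # larger overlap
  pd[2:13, 11:13, 2] <- 2L  # smaller overlap
  gtM <- InstanceMask(gt, sp); pdM <- InstanceMask(pd, sp)
  tb <- matchLesions(gtM, pdM)
  seg <- segmentationMetrics(list(list(gt = gtM, pred = pdM)), list(tb),
                             sizeFilter(0))
  expect_equal(seg$dscLesion, max(tb@pairs$dsc))  # highest DSC kept
  expect_equal(seg$hd95Lesion, min(tb@pairs$hd95))
  # identical masks give (1, 1, 0)
  seg1 <- segmentationMetrics(list(list(gt = gtM, pred = gtM)), NULL,
                              sizeFilter(0))
  expect_equal(seg1$dscImage, 1)
  expect_equal(seg1$dscLesion, 1)
  expect_equal(seg1$hd95Lesion, 0)
})

test_that("segmentation metrics match hand computation on a 3-case cohort", {
  sp <- c(1, 1, 1)
  mk <- function(f) { a <- array(0L, c(16, 16, 4)); f(a) }
  gt1 <- mk(function(a) { a[2:12, 2:12, 2] <- 1L; a })
  pd1 <- gt1                                        # perfect
  gt2 <- mk(function(a) { a[2:12, 2:12, 2] <- 1L; a })
  pd2 <- mk(function(a) { a[2:12, 2:7, 2] <- 1L; a })  # partial
  gt3 <- mk(function(a) { a[2:12, 2:12, 2] <- 1L; a })
  pd3 <- mk(function(a) a)                          # miss
  cases <- list(list(gt = InstanceMask(gt1, sp), pred = InstanceMask(pd1, sp)),
                list(gt = InstanceMask(gt2, sp), pred = InstanceMask(pd2, sp)),
                list(gt = InstanceMask(gt3, sp), pred = InstanceMask(pd3, sp)))
  seg <- segmentationMetrics(cases, NULL, sizeFilter(0))
  d2 <- 2 * sum(gt2 & pd2) / (sum(gt2) + sum(pd2))
  expect_equal(seg$dscImage, mean(c(1, d2, 0)))
  expect_equal(seg$dscLesion, mean(c(1, d2, 0)))
  expect_identical(seg$nHd95, 2L)  # the missed lesion contributes no Hd-95
})

test_that("metrics are invariant to instance relabeling", {
  withr::with_seed(23, {
    gt <- oracleLabel26(randomMask(c(14, 14, 8), 0.1))
    pd <- oracleLabel26(randomMask(c(14, 14, 8), 0.1))
    sp <- c(2, 2, 2)
    gtA <- InstanceMask(gt, sp); pdA <- InstanceMask(pd, sp)
    relab <- function(arr) {
      n <- max(arr)
      if (n < 2) return(arr)
      perm <- sample(n)
      out <- arr
      out[arr > 0] <- perm[arr[arr > 0]]
      out
    }
    gtB <- InstanceMask(relab(gt), sp); pdB <- InstanceMask(relab(pd), sp)
    fA <- sizeFilter(0)
    dA <- detectionMetrics(list(matchLesions(gtA, pdA)), fA)
    dB <- detectionMetrics(list(matchLesions(gtB, pdB)), fA)
    expect_equal(dA[c("F1", "precision", "recall")],
                 dB[c("F1", "precision", "recall")])
    sA <- segmentationMetrics(list(list(gt = gtA, pred = pdA)), NULL, fA)
    sB <- segmentationMetrics(list(list(gt = gtB, pred = pdB)), NULL, fA)
    expect_equal(sA$dscImage, sB$dscImage)
    expect_equal(sA$dscLesion, sB$dscLesion)
  })
})

test_that("FROC endpoints behave at extreme thresholds", {
  sp <- c(1, 1, 1)
  gt <- array(0L, c(20, 20, 4)); gt[2:8, 2:8, 2] <- 1L
  pd <- array(0L, c(20, 20, 4))
  pd[2:8, 2:8, 2] <- 1L   # TP, score 0.9
  pd[12:14, 12:14, 2] <- 2L  # FP, score 0.4
  tb <- matchLesions(InstanceMask(gt, sp), InstanceMask(pd, sp))
  fr <- frocCurve(list(tb), list(c(0.9, 0.4)), sizeFilter(0))
  expect_equal(fr$fpPerScan[nrow(fr)], 1)       # everything kept
  expect_equal(fr$sensitivity[nrow(fr)], 1)
  expect_equal(fr$fpPerScan[1], 0)              # everything dropped
  expect_equal(fr$sensitivity[1], 0)
  # separable scores: an operating point with sensitivity 1 at 0 FP/scan
  expect_true(any(fr$sensitivity == 1 & fr$fpPerScan == 0))
  expect_error(frocCurve(list(tb), list(numeric(0))), "no candidate scores")
})

test_that("volume agreement recovers exact and offset relationships", {
  gt <- c(0.2, 0.5, 0.9, 1.4)
  va <- volumeAgreement(gt, gt)
  expect_equal(va$r2, 1)
  expect_equal(va$bias, 0)
  expect_equal(va$loaLow, 0); expect_equal(va$loaHigh, 0)
  vb <- volumeAgreement(gt + 0.05, gt)
  expect_equal(vb$bias, 0.05)
  expect_equal(vb$loaHigh - vb$loaLow, 0)
  expect_equal(vb$r2, 1)
  withr::with_seed(41, {
    x <- stats::rnorm(12, 1, 0.3)
    y <- x + stats::rnorm(12, 0.02, 0.05)
    vc <- volumeAgreement(y, x)
    fit <- stats::lm(y ~ x)
    expect_equal(vc$r2, summary(fit)$r.squared, tolerance = 1e-9)
    d <- y - x
    expect_equal(vc$bias, mean(d), tolerance = 1e-12)
    expect_equal(vc$loaHigh, mean(d) + 1.96 * stats::sd(d), tolerance = 1e-12)
  })
  expect_error(volumeAgreement(c(1, 2), c(1, 2)), "at least 3")
  expect_error(volumeAgreement(c(1, 2, 3), c(1, 1, 1)), "zero variance")
})

test_that("bootstrap CIs are seed-deterministic and collapse on constants", {
  cases <- as.list(rep(3.5, 10))
  ci <- bootstrapCi(function(cs) mean(unlist(cs)), cases, 200, seed = 9)
  expect_equal(ci$mean, 3.5)
  expect_equal(ci$lo, 3.5); expect_equal(ci$hi, 3.5)
  withr::with_seed(1, x <- stats::rnorm(30))
  a <- bootstrapCi(function(cs) mean(unlist(cs)), as.list(x), 300, seed = 4)
  b <- bootstrapCi(function(cs) mean(unlist(cs)), as.list(x), 300, seed = 4)
  expect_identical(a, b)
  c2 <- bootstrapCi(function(cs) mean(unlist(cs)), as.list(x), 300, seed = 5)
  expect_false(identical(a$lo, c2$lo))
})
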