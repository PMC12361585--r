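# Thoracic bounding box: tight boxes, the per-dimension minimum-size
# fallback, and crop/pad round trips.

test_that("lung bbox is the tight foreground box", {
  arr <- array(0L, c(40, 40, 40))
  arr[10, 20, 30] <- 1L
  m <- BinaryMask(arr, spacing = c(1, 1, 1))
  b <- lungBbox(m)
  expect_identical(b@lo, c(10L, 20L, 30L))
  expect_identical(b@hi, c(10L, 20L, 30L))

  full <- BinaryMask(array(1L, c(5, 6, 7)))
  bf <- lungBbox(full)
  expect_identical(bf@lo, c(1L, 1L, 1L))
  expect_identical(bf@hi, c(5L, 6L, 7L))

  expect_null(lungBbox(BinaryMask(array(0L, c(4, 4, 4)))))

  withr::with_seed(8, {
    for (i in 1:20) {
      a <- randomMask(c(16, 12, 10), p = 0.05)
      ref <- oracleBbox(a)
      got <- lungBbox(BinaryMask(a))
      if (is.null(ref)) {
        expect_null(got)
      } else {
        expect_identical(as.integer(ref$lo), got@lo)
        expect_identical(as.integer(ref$hi), got@hi)
      }
    }
  })
})

test_that("minimum fallback replaces exactly the sub-minimum axes", {
  # 400 mm cube at 5 mm spacing; lung box of physical size 300 x 200 x 100
  grid <- CTVolume(array(0, c(80, 80, 80)), spacing = c(5, 5, 5))
  box <- BoundingBox3D(c(11, 11, 11), c(70, 50, 30))
  expect_equal(unname(boxExtentMm(box, c(5, 5, 5))), c(300, 200, 100))
  out <- applyMinimumFallback(box, grid, bboxConfig())
  # x (300 >= 210) and y (200 >= 150) kept; z (100 < 120) -> whole image
  expect_identical(out@lo, c(11L, 11L, 1L))
  expect_identical(out@hi, c(70L, 50L, 80L))

  # a box meeting all minima is returned unchanged
  big <- BoundingBox3D(c(1, 1, 1), c(60, 60, 40))
  expect_identical(applyMinimumFallback(big, grid, bboxConfig())@hi,
                   big@hi)

  # empty marker -> full grid
  e <- applyMinimumFallback(NULL, grid, bboxConfig())
  expect_identical(e@lo, c(1L, 1L, 1L))
  expect_identical(e@hi, c(80L, 80L, 80L))
})

test_that("fallback is idempotent and monotone over random cases", {
  withr::with_seed(12, {
    for (i in 1:50) {
      shp <- sample(20:60, 3, replace = TRUE)
      sp <- stats::runif(3, 2, 8)
      grid <- CTVolume(array(0, shp), spacing = sp)
      lo <- vapply(shp, function(n) sample.int(n, 1), integer(1))
      hi <- pmin(shp, lo + vapply(shp, function(n) sample.int(n, 1),
                                  integer(1)))
      box <- BoundingBox3D(pmin(lo, hi), pmax(lo, hi))
      f1 <- applyMinimumFallback(box, grid, bboxConfig())
      f2 <- applyMinimumFallback(f1, grid, bboxConfig())
      expect_identical(f1@lo, f2@lo)
      expect_identical(f1@hi, f2@hi)
      # per axis: output meets the minimum or spans the whole grid
      ext <- boxExtentMm(f1, sp)
      for (a in 1:3)
        expect_true(ext[a] >= bboxConfig()@minExtentMm[a] ||
                      (f1@lo[a] == 1L && f1@hi[a] == shp[a]))
      # extensive: the fallback result always contains its input box
      expect_true(all(f1@lo <= box@lo) && all(f1@hi >= box@hi))
      # monotone while the enlargement stays on the same side of the
      # per-axis minimum (crossing it legitimately switches an axis from
      # the full-image range back to the tight box)
      lo2 <- pmax(1L, box@lo - sample(0:3, 3, replace = TRUE))
      hi2 <- pmin(shp, box@hi + sample(0:3, 3, replace = TRUE))
      box2 <- BoundingBox3D(lo2, hi2)
      ext1 <- boxExtentMm(box, sp)
      ext2 <- boxExtentMm(box2, sp)
      sameSide <- all((ext1 < bboxConfig()@minExtentMm) ==
                        (ext2 < bboxConfig()@minExtentMm))
      if (sameSide) {
        g1 <- applyMinimumFallback(box2, grid, bboxConfig())
        expect_true(all(g1@lo <= f1@lo) && all(g1@hi >= f1@hi))
      }
    }
  })
})

test_that("crop and pad are exact inverses on the crop support", {
  withr::with_seed(3, {
    v <- InstanceMask(array(sample(0:2, 24 * 20 * 16, replace = TRUE),
                            c(24, 20, 16)), spacing = c(2, 2, 3))
    box <- BoundingBox3D(c(3, 5, 2), c(20, 18, 11))
    crop <- cropToBox(v, box)
    expect_identical(dim(voxelData(crop)), c(18L, 14L, 10L))
    # origin shifts by the crop offset
    expect_equal(voxelOrigin(crop), (box@lo - 1) * voxelSpacing(v))
    rec <- cropRecordOf(box, v)
    back <- padToOriginal(crop, rec)
    expect_identical(dim(voxelData(back)), dim(voxelData(v)))
    expect_equal(voxelOrigin(back), voxelOrigin(v))
    # equals the input masked to the box
    ref <- array(0L, dim(voxelData(v)))
    ref[3:20, 5:18, 2:11] <- voxelData(v)[3:20, 5:18, 2:11]
    expect_identical(voxelData(back), ref)
    # foreground conserved through crop -> pad
    expect_identical(sum(voxelData(back) != 0), sum(voxelData(crop) != 0))
    # full-grid box is the identity
    idc <- cropToBox(v, fullGridBox(v))
    expect_identical(voxelData(idc), voxelData(v))
  })
  expect_error(cropToBox(CTVolume(array(0, c(4, 4, 4))),
                         BoundingBox3D(c(1, 1, 1), c(5, 4, 4))),
               "out of bounds")
})

test_that("the fallback box preserves wall-attached lesions that the raw lung box truncates", {
  cs <- generatePhantom(tinySpec(seed = 55, nLesions = 1,
                                 pWallAttached = 1, noiseSd = 0))
  ct <- phantomCt(cs)
  lesion <- voxelData(phantomGt(cs)) == 1
  masker <- referenceLungMasker(ct)
  rawBox <- lungBbox(masker)
  fbBox <- applyMinimumFallback(rawBox, ct, bboxConfig())
  inBox <- function(b) {
    sub <- lesion[b@lo[1]:b@hi[1], b@lo[2]:b@hi[2], b@lo[3]:b@hi[3]]
    sum(sub)
  }
  expect_identical(inBox(fbBox), sum(lesion))
  expect_lte(inBox(rawBox), inBox(fbBox))
})
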