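# Internal numeric helpers.

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Separable Gaussian smoothing of a 3-D array; sigma in mm, converted to
# voxels per axis. sigma may be scalar or length 3.
.gaussSmooth <- function(arr, spacing, sigmaMm) {
  sigmaMm <- rep_len(sigmaMm, 3L)
  d <- dim(arr)
  out <- as.numeric(arr)
  for (a in 1:3) {
    sVox <- sigmaMm[a] / spacing[a]
    if (sVox < 1e-6) next
    half <- max(1L, as.integer(ceiling(3 * sVox)))
    k <- stats::dnorm(seq(-half, half), sd = sVox)
    k <- k / sum(k)
    out <- .convolve_axis(out, as.integer(d), k, a - 1L)
  }
  array(out, d)
}

# 26-connectivity labeling of a 0/1 array -> integer array + component count.
.label26 <- function(arr) {
  d <- dim(arr)
  v <- .cc26_label(as.integer(arr != 0), as.integer(d))
  n <- attr(v, "n_components")
  lab <- array(as.integer(v), d)
  attr(lab, "n_components") <- n
  lab
}

.dilateArr <- function(arr, iter = 1L) {
  d <- dim(arr)
  array(.dilate_box(as.integer(arr != 0), as.integer(d), as.integer(iter)), d)
}

.erodeArr <- function(arr, iter = 1L) {
  d <- dim(arr)
  array(.erode_box(as.integer(arr != 0), as.integer(d), as.integer(iter)), d)
}

# Morphological closing (dilate then erode), box structuring element.
.closeArr <- function(arr, iter = 1L) .erodeArr(.dilateArr(arr, iter), iter)

# Physical voxel-center coordinates (mm) of 1-based indices `ijk` (n x 3).
.voxelCenters <- function(ijk, spacing, origin) {
  sweep(sweep(ijk - 1, 2, spacing, `*`), 2, origin, `+`)
}

# min-max normalization to [0,1]; constant input maps to 0.
.minMax01 <- function(x) {
  r <- range(x)
  if (!is.finite(r[1]) || r[2] - r[1] < 1e-12) return(x * 0)
  (x - r[1]) / (r[2] - r[1])
}

# Area under the ROC curve for scores/labels (rank formula would do, but the
# field-standard implementation is preferred for reporting).
.auroc <- function(scores, labels) {
  if (length(unique(labels)) < 2L) stop("AUROC needs both classes")
  as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}
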