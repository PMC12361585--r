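# Accessors and show methods for the spatial containers.

#' Voxel array of a grid object
#' @param x a [VoxelGrid-class] derivative.
#' @return the 3-D array.
#' @export
setMethod("voxelData", "VoxelGrid", function(x) x@data)

#' Voxel spacing in mm
#' @param x a [VoxelGrid-class] derivative.
#' @return numeric(3).
#' @export
setMethod("voxelSpacing", "VoxelGrid", function(x) x@spacing)

#' Physical origin in mm
#' @param x a [VoxelGrid-class] derivative.
#' @return numeric(3).
#' @export
setMethod("voxelOrigin", "VoxelGrid", function(x) x@origin)

#' Grid shape (voxels per axis)
#' @param x a [VoxelGrid-class] derivative.
#' @return integer(3).
#' @export
setMethod("gridShape", "VoxelGrid", function(x) dim(x@data))

#' Physical extent of a volume along one or all axes
#'
#' The extent along axis `a` is `shape[a] * spacing[a]` mm.
#'
#' @param x a [VoxelGrid-class] derivative.
#' @param axis `"x"`, `"y"`, `"z"`, an index 1-3, or `NULL` for all three.
#' @return extent(s) in mm.
#' @examples
#' ct <- CTVolume(array(0, c(512, 512, 100)), spacing = c(0.78, 0.78, 2.5))
#' physicalExtent(ct, "x")  # 399.36 mm
#' @export
setMethod("physicalExtent", "VoxelGrid", function(x, axis = NULL) {
  ext <- dim(x@data) * x@spacing
  names(ext) <- c("x", "y", "z")
  if (is.null(axis)) return(ext)
  if (is.character(axis)) axis <- match(axis, c("x", "y", "z"))
  if (is.na(axis) || axis < 1 || axis > 3) stop("axis must be x, y or z")
  unname(ext[axis])
})

#' Number of lesion instances in an instance mask
#' @param x an [InstanceMask-class].
#' @return integer count of distinct positive labels.
#' @export
setMethod("nInstances", "InstanceMask", function(x) {
  length(instanceLabels(x))
})

#' Sorted distinct positive labels of an instance mask
#' @param x an [InstanceMask-class].
#' @return integer vector of labels (contiguous `1..n` for masks produced
#'   by [labelInstances()] or [runCfpr()]; possibly gapped after a crop).
#' @export
instanceLabels <- function(x) {
  v <- x@data
  sort(unique(v[v > 0]))
}

#' Check two grid objects for grid congruence (same shape, spacing, origin)
#'
#' All stages pairing a volume with a mask require congruent grids; spacing
#' and origin are compared to 1e-6 mm.
#'
#' @param a,b [VoxelGrid-class] derivatives.
#' @return logical.
#' @export
gridCongruent <- function(a, b) {
  identical(dim(a@data), dim(b@data)) &&
    all(abs(a@spacing - b@spacing) < 1e-6) &&
    all(abs(a@origin - b@origin) < 1e-6)
}

.stopIfIncongruent <- function(a, b, what = "volume and mask") {
  if (!gridCongruent(a, b))
    stop("grid-incongruent ", what, ": shape/spacing/origin must match")
  invisible(TRUE)
}

setMethod("show", "VoxelGrid", function(object) {
  d <- dim(object@data)
  cat(class(object), ": ", paste(d, collapse = " x "),
      " voxels @ (", paste(format(object@spacing, digits = 4), collapse = ", "),
      ") mm\n", sep = "")
  cat("  extent: ",
      paste(format(d * object@spacing, digits = 5), collapse = " x "),
      " mm; origin (", paste(format(object@origin, digits = 4),
                             collapse = ", "), ") mm\n", sep = "")
  if (is(object, "InstanceMask"))
    cat("  instances: ", nInstances(object), "\n", sep = "")
  if (is(object, "CTVolume"))
    cat("  HU range: [", format(min(object@data), digits = 5), ", ",
        format(max(object@data), digits = 5), "]\n", sep = "")
})

setMethod("show", "BoundingBox3D", function(object) {
  cat("BoundingBox3D: lo (", paste(object@lo, collapse = ", "),
      ") -- hi (", paste(object@hi, collapse = ", "), ")  [",
      paste(object@hi - object@lo + 1L, collapse = " x "), " voxels]\n",
      sep = "")
})

setMethod("show", "PhantomCase", function(object) {
  cat("PhantomCase: ", paste(dim(object@ct@data), collapse = " x "),
      " voxels, ", nrow(object@lesionInfo), " lesion(s), ",
      nrow(object@distractorInfo), " distractor(s)\n", sep = "")
})

setMethod("show", "MatchTable", function(object) {
  cat("MatchTable: ", nrow(object@gtInfo), " gt lesion(s), ",
      nrow(object@predInfo), " predicted lesion(s), ",
      nrow(object@pairs), " overlapping pair(s)\n", sep = "")
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport\n")
  cat(sprintf("  detection:    F1 %.3f  precision %.3f  recall %.3f\n",
              object@detection$F1, object@detection$precision,
              object@detection$recall))
  cat(sprintf("  segmentation: DSC(image) %.3f  DSC(lesion) %.3f  Hd-95 %.2f mm\n",
              object@segmentation$dscImage, object@segmentation$dscLesion,
              object@segmentation$hd95Lesion))
  if (length(object@volume))
    cat(sprintf("  volume:       R2 %.3f  bias %.4f L  LoA [%.4f, %.4f] L\n",
                object@volume$r2, object@volume$bias, object@volume$loaLow,
                object@volume$loaHigh))
  if (nrow(object@bootstrap)) {
    cat("  bootstrap 95% CIs:\n")
    for (i in seq_len(nrow(object@bootstrap)))
      cat(sprintf("    %-12s %.3f (%.3f-%.3f)\n",
                  object@bootstrap$metric[i], object@bootstrap$mean[i],
                  object@bootstrap$lo[i], object@bootstrap$hi[i]))
  }
})

# Extract the ct/gt/lung components of a PhantomCase.

#' @rdname PhantomCase-class
#' @param case a [PhantomCase-class].
#' @export
phantomCt <- function(case) case@ct

#' @rdname PhantomCase-class
#' @export
phantomGt <- function(case) case@gtLesions

#' @rdname PhantomCase-class
#' @export
phantomLung <- function(case) case@lungMask

#' @rdname PhantomCase-class
#' @export
lesionInfo <- function(case) case@lesionInfo

#' @rdname PhantomCase-class
#' @export
distractorInfo <- function(case) case@distractorInfo
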