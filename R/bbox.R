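# Stage 1: thoracic crop box from a lung mask, with the per-dimension
# minimum-size fallback. A predicted lung box that is implausibly small
# along an axis (smaller than the minimum adult lung extent: 21, 15 and
# 12 cm for x, y, z) is replaced by the whole image along that axis only.

#' Tight bounding box of a mask's foreground
#'
#' @param mask a [BinaryMask-class] (or [InstanceMask-class]; any positive
#'   label counts as foreground).
#' @return a [BoundingBox3D-class], or `NULL` when the mask has no
#'   foreground (the distinguished empty marker).
#' @export
lungBbox <- function(mask) {
  stopifnot(is(mask, "VoxelGrid"))
  arr <- mask@data
  fg <- which(arr != 0)
  if (length(fg) == 0) return(NULL)
  d <- dim(arr)
  ijk <- arrayInd(fg, d)
  BoundingBox3D(lo = apply(ijk, 2, min), hi = apply(ijk, 2, max))
}

#' Physical side lengths of a bounding box, in mm
#'
#' Inclusive corners: side length along axis a is
#' `(hi[a] - lo[a] + 1) * spacing[a]`.
#'
#' @param box a [BoundingBox3D-class].
#' @param spacing numeric(3) voxel spacing in mm.
#' @return numeric(3) of physical side lengths.
#' @export
boxExtentMm <- function(box, spacing) {
  (box@hi - box@lo + 1L) * spacing
}

#' Apply the per-dimension minimum-size fallback to a lung bounding box
#'
#' For each axis independently: if the box's physical side length is
#' smaller than the configured minimum for that axis, the whole image
#' range is used for that axis instead; other axes are untouched. The
#' empty marker (`NULL`, a lung masker that found nothing) maps to the
#' full-grid box. The operation is idempotent, and a full grid smaller
#' than the minimum is legal output (the rule substitutes the whole image,
#' it never errors).
#'
#' @param box a [BoundingBox3D-class] or `NULL`.
#' @param grid the [VoxelGrid-class] the box lives on.
#' @param cfg a [BboxConfig-class].
#' @return a [BoundingBox3D-class].
#' @export
applyMinimumFallback <- function(box, grid, cfg = bboxConfig()) {
  shape <- dim(grid@data)
  if (is.null(box)) return(BoundingBox3D(c(1, 1, 1), shape))
  stopifnot(all(box@hi <= shape))
  lo <- box@lo
  hi <- box@hi
  ext <- boxExtentMm(box, grid@spacing)
  for (a in 1:3) {
    if (ext[a] < cfg@minExtentMm[a]) {
      lo[a] <- 1L
      hi[a] <- shape[a]
    }
  }
  BoundingBox3D(lo, hi)
}

#' Crop a volume or mask to a bounding box
#'
#' The origin is shifted so physical coordinates are preserved. The crop
#' record needed to pad results back ([padToOriginal()]) is available via
#' [cropRecordOf()].
#'
#' @param v a [CTVolume-class], [BinaryMask-class] or [InstanceMask-class].
#' @param box a [BoundingBox3D-class] within the grid.
#' @return the cropped object, same class as `v`.
#' @export
cropToBox <- function(v, box) {
  stopifnot(is(v, "VoxelGrid"))
  shape <- dim(v@data)
  if (any(box@lo < 1L) || any(box@hi > shape))
    stop("box out of bounds")
  arr <- v@data[box@lo[1]:box@hi[1], box@lo[2]:box@hi[2],
                box@lo[3]:box@hi[3], drop = FALSE]
  origin <- v@origin + (box@lo - 1L) * v@spacing
  out <- v
  out@data <- arr
  out@origin <- origin
  validObject(out)
  out
}

#' Crop record for a box on a given grid
#'
#' @param box the [BoundingBox3D-class] used for cropping.
#' @param grid the original (uncropped) [VoxelGrid-class].
#' @return a [CropRecord-class].
#' @export
cropRecordOf <- function(box, grid) {
  CropRecord(lo = box@lo, originalShape = dim(grid@data))
}

#' Pad a cropped mask (or volume) back onto the original grid
#'
#' Zeros outside the crop; the cropped content is placed at the recorded
#' offsets, so the output shape equals the original shape and foreground is
#' conserved.
#'
#' @param mask a cropped [BinaryMask-class], [InstanceMask-class] or
#'   [CTVolume-class].
#' @param record the [CropRecord-class] from the crop.
#' @param fill background fill value (0 for masks; e.g. -1000 for CT).
#' @return same-kind object on the original grid.
#' @export
padToOriginal <- function(mask, record, fill = 0) {
  stopifnot(is(mask, "VoxelGrid"), is(record, "CropRecord"))
  d <- dim(mask@data)
  lo <- record@lo
  hi <- lo + d - 1L
  if (any(hi > record@originalShape))
    stop("crop record inconsistent with mask shape")
  arr <- array(fill, record@originalShape)
  arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- mask@data
  if (is(mask, "BinaryMask") || is(mask, "InstanceMask"))
    storage.mode(arr) <- "integer"
  out <- mask
  out@data <- arr
  out@origin <- mask@origin - (lo - 1L) * mask@spacing
  validObject(out)
  out
}

#' Full-grid bounding box of a volume
#' @param grid a [VoxelGrid-class].
#' @return a [BoundingBox3D-class] spanning the whole grid.
#' @export
fullGridBox <- function(grid) BoundingBox3D(c(1, 1, 1), dim(grid@data))
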