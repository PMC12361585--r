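# NIfTI-1 input/output. Volumes are carried in the fixed anatomical axis
# order (x = left-right, y = anterior-posterior, z = inferior-superior);
# files with a recognizable orientation are reoriented to RAS on load.

#' Read a 3-D NIfTI volume or mask
#'
#' @param path path to a `.nii` / `.nii.gz` file containing a 3-D
#'   single-channel image.
#' @param as one of `"ct"`, `"binary"`, `"instance"`: the container to
#'   return. `"instance"` accepts either an instance-labeled mask or a
#'   binary mask, in which case instances are re-derived by 26-connectivity
#'   labeling.
#' @return a [CTVolume-class], [BinaryMask-class] or [InstanceMask-class].
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' writeVolume(CTVolume(array(rnorm(8), c(2, 2, 2)), c(0.7, 0.7, 3)), f)
#' readVolume(f)
#' @export
readVolume <- function(path, as = c("ct", "binary", "instance")) {
  as <- match.arg(as)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  # normalize axis order when the header carries an orientation
  ornt <- tryCatch(RNifti::orientation(img), error = function(e) NULL)
  if (!is.null(ornt) && !is.na(ornt) && nzchar(ornt) && ornt != "RAS")
    RNifti::orientation(img) <- "RAS"
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img2 <- array(as.numeric(img), d[1:3])
    attr(img2, "pixdim") <- attr(img, "pixdim")
    img <- img2
    d <- d[1:3]
  }
  if (length(d) != 3L) stop("expected 3D volume, got ", length(d), "D")
  pd <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(pd)) || any(pd <= 0))
    stop("non-positive voxel spacing in NIfTI header")
  xf <- tryCatch(RNifti::xform(img), error = function(e) NULL)
  origin <- if (!is.null(xf)) as.numeric(xf[1:3, 4]) else c(0, 0, 0)
  arr <- array(as.numeric(img), d)
  switch(as,
    ct = CTVolume(arr, spacing = pd, origin = origin),
    binary = {
      if (!all(arr %in% c(0, 1)))
        stop("file does not contain a binary mask")
      BinaryMask(arr, spacing = pd, origin = origin)
    },
    instance = {
      if (any(arr < 0) || any(arr != round(arr)))
        stop("file does not contain an integer label mask")
      labs <- sort(unique(arr[arr > 0]))
      if (length(labs) > 0 && all(labs == 1)) {
        labelInstances(BinaryMask(arr, spacing = pd, origin = origin))
      } else {
        # relabel to contiguous 1..n, preserving label order
        out <- array(match(arr, labs, nomatch = 0L), d)
        InstanceMask(out, spacing = pd, origin = origin)
      }
    })
}

#' Write a volume or mask as NIfTI-1
#'
#' The affine is diagonal in the voxel spacing with the origin in the
#' translation column (RAS). Masks are stored with an integer voxel type.
#'
#' @param v a [CTVolume-class], [BinaryMask-class] or [InstanceMask-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(v, path) {
  stopifnot(is(v, "VoxelGrid"))
  arr <- v@data
  isMask <- is(v, "BinaryMask") || is(v, "InstanceMask")
  datatype <- if (isMask) "uint16" else "float"
  affine <- diag(c(v@spacing, 1))
  affine[1:3, 4] <- v@origin
  img <- RNifti::asNifti(arr,
    reference = list(pixdim = c(-1, v@spacing, 1, 1, 1, 1)),
    datatype = datatype)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path: directory does not exist")
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
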