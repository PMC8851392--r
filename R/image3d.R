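#' Construct a 3D image
#'
#' A minimal container for a co-registered scalar volume: a 3D numeric array
#' plus per-axis voxel spacing in millimetres. Used for PET activity images,
#' binary segmentation masks and smoothed probability maps. All geometry in
#' the package is derived from `spacing`; voxel indices are treated as
#' 0-based offsets from `origin` when converted to mm.
#'
#' @param voxels 3D numeric array of voxel values.
#' @param spacing numeric length-3, voxel size in mm per axis; all > 0.
#' @param origin numeric length-3 world position of voxel (1,1,1) in mm.
#' @return An object of class `image3d`.
#' @examples
#' img <- image3d(array(0, c(4, 4, 4)), spacing = c(2, 2, 2))
#' dim(img$voxels)
#' @export
image3d <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    abort("expected 3D volume")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("spacing must be 3 positive finite values (mm)")
  }
  if (any(!is.finite(voxels))) {
    abort("voxel values must be finite")
  }
  structure(
    list(voxels = voxels, spacing = spacing, origin = as.numeric(origin)),
    class = "image3d"
  )
}

#' @export
print.image3d <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<image3d> %d x %d x %d voxels @ %.4g x %.4g x %.4g mm\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  cat(sprintf(
    "  range [%.4g, %.4g]\n",
    min(x$voxels), max(x$voxels)
  ))
  invisible(x)
}

#' @export
dim.image3d <- function(x) dim(x$voxels)

#' Read a 3D volume from a NIfTI file
#'
#' @param path path to a `.nii` or `.nii.gz` file containing a 3D volume.
#' @return An [image3d()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  nii <- RNifti::readNifti(path)
  arr <- as.array(nii)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) {
    arr <- arr[, , , 1, drop = TRUE]
    dim(arr) <- dim(arr)[1:3]
  }
  if (length(dim(arr)) != 3L) abort("expected 3D volume")
  pd <- RNifti::pixdim(nii)[1:3]
  image3d(arr, spacing = pd)
}

#' Write a 3D volume to a NIfTI file
#'
#' Values are stored as 64-bit floats so that a read/write round trip is
#' bit-exact.
#'
#' @param img an [image3d()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(img, path) {
  stopifnot(inherits(img, "image3d"))
  nii <- RNifti::asNifti(img$voxels)
  RNifti::pixdim(nii) <- img$spacing
  RNifti::writeNifti(nii, path, datatype = "double")
  invisible(path)
}

#' Assert that two volumes live on the same voxel grid
#'
#' The pipeline assumes co-registered, same-grid inputs (no resampling is
#' performed). Shapes must match exactly and spacings to within `tol` mm.
#'
#' @param a,b [image3d()] objects.
#' @param tol spacing tolerance in mm.
#' @return `TRUE` invisibly, or an error naming the differing axis.
#' @export
assert_same_grid <- function(a, b, tol = 1e-4) {
  da <- dim(a$voxels); db <- dim(b$voxels)
  for (ax in 1:3) {
    if (da[ax] != db[ax]) {
      abort(sprintf(
        "grid mismatch on axis %d: shape %d vs %d", ax, da[ax], db[ax]
      ))
    }
  }
  for (ax in 1:3) {
    if (abs(a$spacing[ax] - b$spacing[ax]) > tol) {
      abort(sprintf(
        "grid mismatch on axis %d: spacing %.6g vs %.6g mm",
        ax, a$spacing[ax], b$spacing[ax]
      ))
    }
  }
  invisible(TRUE)
}

# mask with values in {0,1} (exact)
is_binary_mask <- function(img) {
  all(img$voxels %in% c(0, 1))
}
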