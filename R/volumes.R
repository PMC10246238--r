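#' Binary mask volumes and weighted maps
#'
#' The package represents every volume as a plain list holding a 3D array
#' (`grid`) and a 4x4 voxel-to-world affine (`affine`, mm units, RAS+ world
#' axes, 0-based voxel indices at voxel centers). Two classes share this
#' layout: `lesion_mask` (strictly binary grids: lesions and ROIs) and
#' `weighted_map` (nonnegative real grids: statistical maps). Both inherit
#' from `lesion_volume`.
#'
#' @param grid 3D numeric array.
#' @param affine 4x4 voxel-to-world transform; last row `(0,0,0,1)`.
#' @return `lesion_mask()` returns an object of class
#'   `c("lesion_mask","lesion_volume")`; `weighted_map()` one of class
#'   `c("weighted_map","lesion_volume")`.
#' @examples
#' g <- array(0L, dim = c(8, 8, 8)); g[3:5, 3:5, 3:5] <- 1L
#' m <- lesion_mask(g, diag(4))
#' volume_mm3(m)
#' @export
lesion_mask <- function(grid, affine = diag(4)) {
  v <- new_volume(grid, affine)
  if (!all(v$grid %in% c(0, 1)))
    stopf("mask grid must be strictly binary {0,1}")
  v$grid <- array(as.integer(v$grid), dim = dim(v$grid))
  class(v) <- c("lesion_mask", "lesion_volume")
  v
}

#' @rdname lesion_mask
#' @export
weighted_map <- function(grid, affine = diag(4)) {
  v <- new_volume(grid, affine)
  if (any(!is.finite(v$grid)) || any(v$grid < 0))
    stopf("weighted map values must be finite and >= 0")
  class(v) <- c("weighted_map", "lesion_volume")
  v
}

new_volume <- function(grid, affine) {
  if (length(dim(grid)) != 3L) stopf("volume must be 3D (got %d dims)",
                                     length(dim(grid)))
  affine <- validate_affine(affine)
  list(grid = grid, affine = affine)
}

validate_affine <- function(affine) {
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stopf("affine must be a 4x4 matrix")
  if (max(abs(affine[4, ] - c(0, 0, 0, 1))) > 1e-8)
    stopf("affine last row must be (0,0,0,1)")
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    stopf("degenerate affine: voxel axes are not invertible")
  storage.mode(affine) <- "double"
  affine
}

#' Voxel dimensions and volume of a mask
#'
#' `voxel_size()` returns the edge lengths (mm) of a voxel, i.e. the column
#' norms of the affine's 3x3 block; `volume_mm3()` the mask volume, voxel
#' count times voxel volume.
#'
#' @param x a `lesion_mask` or `weighted_map`.
#' @return `voxel_size()`: numeric length 3; `volume_mm3()`: scalar mm^3.
#' @export
voxel_size <- function(x) {
  sqrt(colSums(x$affine[1:3, 1:3]^2))
}

#' @rdname voxel_size
#' @export
volume_mm3 <- function(x) {
  stopifnot(inherits(x, "lesion_mask"))
  sum(x$grid) * prod(voxel_size(x))
}

#' @export
print.lesion_volume <- function(x, ...) {
  kind <- if (inherits(x, "lesion_mask")) "binary mask" else "weighted map"
  cat(sprintf("<%s> %s, voxels %.3g x %.3g x %.3g mm\n", kind,
              paste(dim(x$grid), collapse = " x "),
              voxel_size(x)[1], voxel_size(x)[2], voxel_size(x)[3]))
  if (inherits(x, "lesion_mask"))
    cat(sprintf("  %d foreground voxels, %.0f mm^3\n", sum(x$grid),
                volume_mm3(x)))
  else
    cat(sprintf("  value range [%.4g, %.4g], total weight %.4g\n",
                min(x$grid), max(x$grid), sum(x$grid)))
  invisible(x)
}

#' Read and write NIfTI-1 volumes
#'
#' `read_mask()` loads a NIfTI-1 volume, reorients it to RAS+ where the
#' header permits, and binarizes it: values strictly greater than
#' `binarize_threshold` become 1. `read_weighted_map()` loads a nonnegative
#' real-valued map the same way without binarization. `write_volume()`
#' writes either class back to NIfTI-1 (sform/qform set from the affine);
#' a read-write-read round trip preserves grid and affine to well below
#' 1e-6.
#'
#' @param path NIfTI-1 file (`.nii` or `.nii.gz`).
#' @param binarize_threshold nonnegative scalar; default 0.5.
#' @return a `lesion_mask` / `weighted_map`; `write_volume()` returns
#'   `path` invisibly.
#' @export
read_mask <- function(path, binarize_threshold = 0.5) {
  if (binarize_threshold < 0) stopf("binarize_threshold must be >= 0")
  v <- read_nifti_ras(path)
  lesion_mask(array(as.integer(v$grid > binarize_threshold),
                    dim = dim(v$grid)), v$affine)
}

#' @rdname read_mask
#' @export
read_weighted_map <- function(path) {
  v <- read_nifti_ras(path)
  weighted_map(v$grid, v$affine)
}

read_nifti_ras <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stopf("unreadable NIfTI header/data in '%s': %s",
                                            path, conditionMessage(e)))
  if (length(dim(img)) != 3L)
    stopf("'%s' is not a 3D volume (got %d dims)", path, length(dim(img)))
  RNifti::orientation(img) <- "RAS"
  aff <- RNifti::xform(img)
  grid <- array(as.numeric(img), dim = dim(img))
  list(grid = grid, affine = validate_affine(unclass(aff)[1:4, 1:4]))
}

#' @rdname read_mask
#' @param x a `lesion_mask` or `weighted_map` to write.
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, "lesion_volume"))
  img <- RNifti::asNifti(x$grid)
  RNifti::sform(img) <- structure(x$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Compare the grids of two volumes
#'
#' Two volumes are "on the same grid" when their array shapes are equal and
#' their affines agree within `tol` mm elementwise. All pairwise operations
#' (lesion vs ROI, lesion vs map) require this.
#'
#' @param a,b `lesion_mask` or `weighted_map`.
#' @param tol affine tolerance in mm; default 1e-4 (registration jitter far
#'   below analysis resolution).
#' @return logical scalar.
#' @export
check_same_grid <- function(a, b, tol = 1e-4) {
  identical(dim(a$grid), dim(b$grid)) &&
    max(abs(a$affine - b$affine)) <= tol
}

require_same_grid <- function(a, b, what = "volumes") {
  if (!check_same_grid(a, b))
    stopf("grid mismatch: %s are not on the same grid", what)
  invisible(TRUE)
}

#' Nearest-neighbour resampling of a binary mask onto a reference grid
#'
#' Each reference voxel center is mapped through the reference affine to
#' world mm, then through the inverse source affine to a source voxel; the
#' nearest source voxel's value is taken (0 outside the source field of
#' view). Binary data are never interpolated. When source and reference
#' grids already match the mask is returned unchanged (idempotence).
#'
#' @param src `lesion_mask` to resample.
#' @param reference `lesion_mask` or `weighted_map` defining the target grid.
#' @return `lesion_mask` on the reference grid.
#' @export
resample_nearest <- function(src, reference) {
  stopifnot(inherits(src, "lesion_mask"))
  if (check_same_grid(src, reference)) {
    out <- src
    out$affine <- reference$affine
    return(out)
  }
  d <- dim(reference$grid)
  idx0 <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                                k = 0:(d[3] - 1)))
  world <- voxel_to_world(reference$affine, idx0)
  sv <- round(world_to_voxel(src$affine, world))
  sd <- dim(src$grid)
  ok <- sv[, 1] >= 0 & sv[, 1] < sd[1] &
        sv[, 2] >= 0 & sv[, 2] < sd[2] &
        sv[, 3] >= 0 & sv[, 3] < sd[3]
  vals <- integer(nrow(sv))
  vals[ok] <- src$grid[cbind(sv[ok, 1] + 1, sv[ok, 2] + 1, sv[ok, 3] + 1)]
  lesion_mask(array(vals, dim = d), reference$affine)
}
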