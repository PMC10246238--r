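#' Cohort lesion overlap map
#'
#' Voxelwise count of how many subjects' lesions cover each voxel; the
#' standard descriptive map of lesion spatial distribution in a cohort.
#'
#' @param masks nonempty list of `lesion_mask` objects on one grid.
#' @return object of class `c("count_map","lesion_volume")` with integer
#'   `grid`, `affine` and `n_subjects`.
#' @export
overlap_map <- function(masks) {
  if (length(masks) == 0L) stopf("empty mask list")
  stopifnot(all(vapply(masks, inherits, logical(1), "lesion_mask")))
  for (m in masks[-1]) require_same_grid(masks[[1]], m, "cohort masks")
  g <- Reduce(`+`, lapply(masks, `[[`, "grid"))
  structure(list(grid = array(as.integer(g), dim = dim(g)),
                 affine = masks[[1]]$affine,
                 n_subjects = length(masks)),
            class = c("count_map", "lesion_volume"))
}

#' @export
print.count_map <- function(x, ...) {
  cat(sprintf("<count_map> n=%d subjects, max overlap %d\n",
              x$n_subjects, max(x$grid)))
  invisible(x)
}

#' Proportional subtraction map between two lesion groups
#'
#' Voxelwise difference of lesion frequency between a positive (e.g.
#' symptomatic) and negative group, in percentage points:
#' `100 * (count_pos/n_pos - count_neg/n_neg)`, bounded in `[-100, 100]`
#' and zero wherever no lesion occurs in either group. No statistical
#' threshold is applied.
#'
#' @param pos,neg nonempty lists of `lesion_mask` on one grid.
#' @return object of class `c("prop_subtraction_map","lesion_volume")`.
#' @export
proportional_subtraction <- function(pos, neg) {
  if (length(pos) == 0L || length(neg) == 0L)
    stopf("both groups must be nonempty")
  cp <- overlap_map(pos)
  cn <- overlap_map(neg)
  require_same_grid(cp, cn, "group maps")
  g <- 100 * (cp$grid / cp$n_subjects - cn$grid / cn$n_subjects)
  structure(list(grid = g, affine = cp$affine,
                 n_pos = cp$n_subjects, n_neg = cn$n_subjects),
            class = c("prop_subtraction_map", "lesion_volume"))
}

#' @export
print.prop_subtraction_map <- function(x, ...) {
  cat(sprintf("<prop_subtraction_map> n=%d vs n=%d, range [%.1f, %.1f] pp\n",
              x$n_pos, x$n_neg, min(x$grid), max(x$grid)))
  invisible(x)
}

#' World coordinate of a map's peak
#'
#' Locates the maximum-value voxel of any volume (count map, subtraction
#' map, weighted map or mask) and reports its world mm coordinate. Ties are
#' broken toward the lowest linear (column-major) index, so the result is
#' reproducible.
#'
#' @param map a `lesion_volume` with at least one nonzero voxel.
#' @return list with `world_mm` (length-3 mm coordinate of the peak voxel
#'   center), `value`, and `voxel_index` (0-based length-3).
#' @export
peak_coordinate <- function(map) {
  stopifnot(inherits(map, "lesion_volume"))
  if (all(map$grid == 0)) stopf("all-zero map has no peak")
  lin <- which.max(map$grid)  # first max in column-major order
  idx0 <- arrayInd(lin, dim(map$grid)) - 1L
  list(world_mm = drop(voxel_to_world(map$affine, idx0)),
       value = map$grid[lin],
       voxel_index = drop(idx0))
}
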