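#' Partition an ROI into oblique 1 mm slices
#'
#' Assigns every foreground voxel of an ROI to a slice bin along an oblique
#' coronal axis. Slices are coronal planes rotated by `angle_deg` about the
#' left-right (x) world axis, so the slice normal is
#' `n = (0, cos(theta), sin(theta))` with positive angles tilting the normal
#' superiorly. Each ROI voxel center is projected onto `n` and assigned to
#' the nearest bin center; bin centers are spaced `bin_width_mm` apart,
#' anchored at the minimum projection, so bin 0 holds the most
#' inferior-anterior slice. No resampling or interpolation is performed on
#' the binary data. Only occupied bins are emitted.
#'
#' @param roi nonempty `lesion_mask`.
#' @param angle_deg tilt of the slicing axis in degrees, in `[0, 90)`;
#'   0 gives pure coronal slices. The value used throughout the cerebellar
#'   outflow analyses is 17 (slices perpendicular to the superior cerebellar
#'   peduncles), but it is a configuration value, not a constant.
#' @param bin_width_mm slice thickness in mm (> 0), default 1.
#' @return object of class `slice_partition`: `voxel_index` (0-based
#'   n x 3), `projection` (mm), `bin` (integer per voxel), `bin_counts`
#'   (named occupancy table), plus the geometry (`angle_deg`, `normal`,
#'   `bin_width_mm`).
#' @examples
#' g <- array(0L, dim = c(9, 9, 9)); g[5, 3:7, 5] <- 1L
#' sp <- slice_partition(lesion_mask(g), angle_deg = 0)
#' sp$bin_counts
#' @export
slice_partition <- function(roi, angle_deg = 17, bin_width_mm = 1) {
  stopifnot(inherits(roi, "lesion_mask"))
  if (bin_width_mm <= 0) stopf("bin_width_mm must be > 0")
  if (angle_deg < 0 || angle_deg >= 90)
    stopf("angle_deg must be in [0, 90)")
  idx1 <- which(roi$grid == 1L, arr.ind = TRUE)
  if (nrow(idx1) == 0L) stopf("empty ROI")
  idx0 <- idx1 - 1L
  world <- voxel_to_world(roi$affine, idx0)
  theta <- angle_deg * pi / 180
  normal <- c(0, cos(theta), sin(theta))
  proj <- world[, 2] * normal[2] + world[, 3] * normal[3]
  bin <- as.integer(round((proj - min(proj)) / bin_width_mm))
  structure(list(angle_deg = angle_deg, normal = normal,
                 bin_width_mm = bin_width_mm,
                 voxel_index = idx0, projection = proj, bin = bin,
                 bin_counts = table(bin)),
            class = "slice_partition")
}

#' @export
print.slice_partition <- function(x, ...) {
  cat(sprintf("<slice_partition> %d ROI voxels, %d occupied %g mm bins at %g deg\n",
              length(x$bin), length(x$bin_counts), x$bin_width_mm,
              x$angle_deg))
  invisible(x)
}

#' Slice-wise maximum percent-overlap lesion load
#'
#' The ROI lesion-load statistic: the ROI is partitioned into oblique
#' `bin_width_mm` slices at `angle_deg` (see [slice_partition()]); within
#' each slice the percentage of ROI voxels intersected by the lesion is
#' computed, and the maximum over slices is the lesion load. A lesion
#' covering every ROI voxel of some slice scores 100%; a lesion disjoint
#' from the ROI scores 0%.
#'
#' @param lesion binary `lesion_mask`, same grid as `roi`.
#' @param roi nonempty binary `lesion_mask` (e.g. the cerebellar outflow
#'   pathway).
#' @inheritParams slice_partition
#' @param min_roi_voxels_per_bin slices with fewer ROI voxels than this are
#'   dropped from the profile; default 1, i.e. no filtering. Slices with
#'   very few ROI voxels can produce unstable 0/100 percentages.
#' @return object of class `lesion_load_result`: `load_percent` in
#'   `[0, 100]`, `argmax_bin` (smallest bin index attaining the max),
#'   `profile` (named percent per bin), `roi_bin_counts`.
#' @examples
#' g <- array(0L, dim = c(9, 9, 9)); g[5, 3:7, 5] <- 1L
#' roi <- lesion_mask(g)
#' les <- g; les[] <- 0L; les[5, 3, 5] <- 1L
#' outflow_lesion_load(lesion_mask(les), roi, angle_deg = 0)$load_percent
#' @export
outflow_lesion_load <- function(lesion, roi, angle_deg = 17,
                                bin_width_mm = 1,
                                min_roi_voxels_per_bin = 1) {
  stopifnot(inherits(lesion, "lesion_mask"))
  require_same_grid(lesion, roi, "lesion and ROI")
  sp <- slice_partition(roi, angle_deg, bin_width_mm)
  les_at_roi <- lesion$grid[sp$voxel_index + 1L]
  roi_counts <- c(tapply(rep(1L, length(sp$bin)), sp$bin, sum))
  les_counts <- c(tapply(les_at_roi, sp$bin, sum))
  keep <- roi_counts >= min_roi_voxels_per_bin
  if (!any(keep))
    stopf("no slice has >= %d ROI voxels", min_roi_voxels_per_bin)
  roi_counts <- roi_counts[keep]
  les_counts <- les_counts[keep]
  profile <- 100 * les_counts / roi_counts
  bins <- as.integer(names(profile))
  imax <- which(profile == max(profile))
  imax <- imax[which.min(bins[imax])]
  structure(list(load_percent = unname(max(profile)),
                 argmax_bin = bins[imax],
                 profile = profile,
                 roi_bin_counts = roi_counts,
                 angle_deg = angle_deg, bin_width_mm = bin_width_mm),
            class = "lesion_load_result")
}

#' @export
print.lesion_load_result <- function(x, ...) {
  cat(sprintf("<lesion_load_result> load %.1f%% at bin %d (%d slices, %g deg)\n",
              x$load_percent, x$argmax_bin, length(x$profile), x$angle_deg))
  invisible(x)
}

#' Weighted-map lesion load
#'
#' Lesion load against a voxel-weighted statistical map (an a-priori
#' lesion-symptom map): the sum of map weights over lesioned voxels
#' (`raw_sum`), and that sum as a fraction of the total map weight
#' (`normalized_load` in `[0, 1]`). A lesion covering every positive-weight
#' voxel scores 1; an empty lesion scores 0.
#'
#' @param lesion binary `lesion_mask` on the map's grid.
#' @param wmap `weighted_map` with positive total weight.
#' @return object of class `weighted_load_result` with fields `raw_sum` and
#'   `normalized_load`.
#' @export
weighted_map_lesion_load <- function(lesion, wmap) {
  stopifnot(inherits(lesion, "lesion_mask"), inherits(wmap, "weighted_map"))
  require_same_grid(lesion, wmap, "lesion and weighted map")
  total <- sum(wmap$grid)
  if (total <= 0) stopf("all-zero weighted map")
  raw <- sum(wmap$grid[lesion$grid == 1L])
  structure(list(raw_sum = raw, normalized_load = raw / total),
            class = "weighted_load_result")
}

#' @export
print.weighted_load_result <- function(x, ...) {
  cat(sprintf("<weighted_load_result> raw %.4g, normalized %.4g\n",
              x$raw_sum, x$normalized_load))
  invisible(x)
}
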