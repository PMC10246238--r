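test_that("slice_partition geometry matches hand-computed projections", {
  # zero tilt on a 1 mm grid: bins are integer y planes
  roi <- mask_at(rbind(c(3, 2, 4), c(5, 4, 2), c(1, 6, 6)))
  sp <- slice_partition(roi, angle_deg = 0)
  expect_equal(sort(unique(sp$bin)), c(0L, 2L, 4L))  # y0 = 1, 3, 5
  expect_equal(sum(sp$bin_counts), 3L)

  # single-voxel ROI: one bin, one voxel, at any angle
  for (ang in c(0, 17, 45, 80)) {
    sp1 <- slice_partition(mask_at(c(4, 4, 4)), angle_deg = ang)
    expect_equal(length(sp1$bin_counts), 1L)
    expect_equal(unname(sp1$bin_counts[1]), 1L)
  }

  # three collinear voxels at world (y,z) = (0,0), (1,0), (0,1), 17 deg:
  # projections 0, cos17 = 0.9563, sin17 = 0.2924 -> bins {0: 2, 1: 1}
  roi3 <- mask_at(rbind(c(1, 1, 1), c(1, 2, 1), c(1, 1, 2)))
  sp3 <- slice_partition(roi3, angle_deg = 17)
  expect_equal(as.vector(sp3$bin_counts), c(2L, 1L))
  expect_equal(names(sp3$bin_counts), c("0", "1"))
  expect_equal(sort(sp3$projection - min(sp3$projection)),
               c(0, sin(17 * pi / 180), cos(17 * pi / 180)))

  expect_error(slice_partition(blank_mask()), "empty ROI")
  expect_error(slice_partition(roi, bin_width_mm = 0), "bin_width")
  expect_error(slice_partition(roi, angle_deg = 90), "angle")
})

test_that("every ROI voxel lands in exactly one bin", {
  set.seed(42)
  for (ang in c(0, 17, 33)) {
    roi <- random_mask(14, 0.15)
    sp <- slice_partition(roi, angle_deg = ang)
    expect_equal(sum(sp$bin_counts), sum(roi$grid))
    expect_equal(length(sp$bin), sum(roi$grid))
  }
})

test_that("outflow lesion load hits its boundary semantics", {
  roi <- mask_at(rbind(c(3, 4, 5), c(3, 5, 5), c(3, 6, 5)))
  # lesion covering the whole ROI: 100%
  expect_equal(outflow_lesion_load(roi, roi)$load_percent, 100)
  # lesion entirely sparing the ROI: 0%
  spare <- mask_at(c(8, 8, 8))
  expect_equal(outflow_lesion_load(spare, roi)$load_percent, 0)
  # grid mismatch rejected
  expect_error(outflow_lesion_load(blank_mask(12), roi), "grid mismatch")
})

test_that("per-slice percentages match a direct count construction", {
  # tube ROI along y: 5 coronal slices of 10 voxels each on a 20^3 grid
  g <- array(0L, dim = rep(20, 3))
  g[6:10, 8:12, 10:11] <- 1L            # 5 x-by-2 z voxels per y slice
  roi <- lesion_mask(g, diag(4))
  les <- array(0L, dim = rep(20, 3))
  les[6:10, 10, 10] <- 1L; les[6:7, 10, 11] <- 1L  # 7 voxels of slice y=10
  les[6:7, 8, 10] <- 1L                            # 2 voxels of slice y=8
  r <- outflow_lesion_load(lesion_mask(les, diag(4)), roi, angle_deg = 0)
  expect_equal(r$load_percent, 70)
  expect_equal(r$argmax_bin, 2L)       # y = 10 is the third occupied slice
  expect_equal(unname(r$profile[c("0", "2")]), c(20, 70))
  expect_equal(unname(r$roi_bin_counts), rep(10L, 5))
  # agrees with the independent brute-force oracle
  expect_equal(r$load_percent,
               brute_force_load(lesion_mask(les, diag(4)), roi, 0))
})

test_that("argmax ties break toward the smallest bin index", {
  g <- array(0L, dim = rep(10, 3))
  g[5, 3:6, 5] <- 1L
  roi <- lesion_mask(g, diag(4))
  les <- array(0L, dim = rep(10, 3))
  les[5, c(4, 6), 5] <- 1L             # two slices fully covered
  r <- outflow_lesion_load(lesion_mask(les, diag(4)), roi, angle_deg = 0)
  expect_equal(r$load_percent, 100)
  expect_equal(r$argmax_bin, 1L)
})

test_that("load is invariant to a rigid world translation of both volumes", {
  set.seed(5)
  roi <- random_mask(12, 0.2)
  les <- random_mask(12, 0.2)
  base <- outflow_lesion_load(les, roi)$load_percent
  aff <- diag(4); aff[1:3, 4] <- c(-31, 12.5, 4)
  r2 <- outflow_lesion_load(lesion_mask(les$grid, aff),
                            lesion_mask(roi$grid, aff))$load_percent
  expect_equal(r2, base, tolerance = 1e-12)
})

test_that("adding lesion voxels never decreases either load statistic", {
  set.seed(9)
  roi <- random_mask(12, 0.25)
  wmap <- weighted_map(array(runif(12^3), dim = rep(12, 3)))
  for (rep in 1:10) {
    les <- random_mask(12, 0.1)
    grown <- les$grid
    grown[sample(which(grown == 0L), 40)] <- 1L
    grown <- lesion_mask(grown)
    expect_gte(outflow_lesion_load(grown, roi)$load_percent,
               outflow_lesion_load(les, roi)$load_percent)
    expect_gte(weighted_map_lesion_load(grown, wmap)$raw_sum,
               weighted_map_lesion_load(les, wmap)$raw_sum)
  }
})

test_that("sparse slices can be filtered from the profile", {
  g <- array(0L, dim = rep(10, 3))
  g[4:6, 3, 5] <- 1L                   # slice y=3: 3 ROI voxels
  g[5, 6, 5] <- 1L                     # slice y=6: 1 ROI voxel
  roi <- lesion_mask(g)
  les <- mask_at(c(5, 6, 5))           # covers only the 1-voxel slice
  full <- outflow_lesion_load(les, roi, angle_deg = 0)
  expect_equal(full$load_percent, 100)
  filt <- outflow_lesion_load(les, roi, angle_deg = 0,
                              min_roi_voxels_per_bin = 2)
  expect_equal(filt$load_percent, 0)
  expect_error(outflow_lesion_load(les, roi, angle_deg = 0,
                                   min_roi_voxels_per_bin = 5),
               "no slice")
})

test_that("weighted-map lesion load sums map weight over the lesion", {
  g <- array(0, dim = rep(6, 3))
  g[1, 1, 1] <- 2; g[2, 2, 2] <- 3; g[3, 3, 3] <- 5
  wmap <- weighted_map(g, diag(4))
  # lesion on the weight-5 voxel only
  r <- weighted_map_lesion_load(mask_at(c(3, 3, 3), 6), wmap)
  expect_equal(r$raw_sum, 5)
  expect_equal(r$normalized_load, 0.5)
  # full coverage -> 1; empty lesion -> 0
  all3 <- mask_at(rbind(c(1, 1, 1), c(2, 2, 2), c(3, 3, 3)), 6)
  expect_equal(weighted_map_lesion_load(all3, wmap)$normalized_load, 1)
  expect_equal(weighted_map_lesion_load(blank_mask(6), wmap)$raw_sum, 0)
  expect_equal(weighted_map_lesion_load(blank_mask(6), wmap)$normalized_load, 0)
  expect_error(weighted_map_lesion_load(all3,
                 weighted_map(array(0, dim = rep(6, 3)))), "all-zero")
})
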