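# Shared fixtures: all volumes are generated in code at test time.

# Empty mask on an n^3 grid with an identity (1 mm) affine.
blank_mask <- function(n = 10, affine = diag(4)) {
  lesion_mask(array(0L, dim = rep(n, 3)), affine)
}

# Mask with ones at the given 1-based voxel index rows.
mask_at <- function(idx, n = 10, affine = diag(4)) {
  g <- array(0L, dim = rep(n, 3))
  g[matrix(idx, ncol = 3)] <- 1L
  lesion_mask(g, affine)
}

# Random binary mask with approximately `fill` foreground fraction.
random_mask <- function(n = 12, fill = 0.1, affine = diag(4)) {
  g <- array(as.integer(stats::runif(n^3) < fill), dim = rep(n, 3))
  lesion_mask(g, affine)
}

# Small phantom used where the full-size default would be wasteful.
small_phantom <- function() {
  make_phantom(phantom_spec(grid_shape = c(48L, 48L, 48L),
                            cerebellum_semiaxes_mm = c(20, 17, 14),
                            outflow_radius_mm = 2,
                            outflow_halflength_mm = 9,
                            outflow_offset_mm = 4,
                            outflow_center_mm = c(5, 4),
                            vermis_halfwidth_mm = 4))
}

small_cohort_spec <- function(...) {
  cohort_spec(volume_range_mm3 = c(300, 4000), bed_limit_mm = c(-2, -2),
              ...)
}

# Independent brute-force slice-load oracle: explicit per-voxel loop,
# rounding projections onto the tilted normal to the nearest bin center,
# with counts accumulated in an environment-backed tally rather than the
# package's vectorised tapply path.
brute_force_load <- function(lesion, roi, angle_deg = 17, bin_width = 1) {
  th <- angle_deg * pi / 180
  idx <- which(roi$grid == 1L, arr.ind = TRUE)
  proj <- numeric(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    w <- roi$affine %*% c(idx[r, ] - 1, 1)
    proj[r] <- w[2] * cos(th) + w[3] * sin(th)
  }
  bin <- round((proj - min(proj)) / bin_width)
  roi_n <- les_n <- list()
  for (r in seq_len(nrow(idx))) {
    key <- as.character(bin[r])
    roi_n[[key]] <- (roi_n[[key]] %||% 0) + 1
    les_n[[key]] <- (les_n[[key]] %||% 0) +
      lesion$grid[idx[r, 1], idx[r, 2], idx[r, 3]]
  }
  max(vapply(names(roi_n), function(k)
    100 * les_n[[k]] / roi_n[[k]], numeric(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Mean cross-validated correlation under label permutation (null reference).
with_null_perms <- function(lm, y, n_perm = 10, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n_perm), function(p) {
    yp <- sample(y)
    select_sparseness(lm, yp, n_repeats = 10,
                      seed = seed + p)$cv_correlation
  }, numeric(1))
}

# Lesion matrix with one causal column: y equals that column exactly.
planted_matrix <- function(n = 40, p = 30, causal = 7, seed = 1) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 1, 0.3), n, p)
  X[, causal] <- rep(c(0L, 1L), length.out = n)
  list(X = X, y = X[, causal], causal = causal)
}
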