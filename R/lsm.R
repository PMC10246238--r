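#' Build a subjects-by-voxels lesion matrix
#'
#' Stacks binary lesion masks into the design matrix used by multivariate
#' lesion-symptom mapping. Columns are restricted to voxels lesioned in at
#' least `min_coverage` subjects; rarer voxels carry almost no information
#' and inflate the search space.
#'
#' @param masks list of `lesion_mask` on one grid, in cohort row order.
#' @param min_coverage minimum subjects lesioned per retained voxel
#'   (>= 1). The pipeline default is `ceiling(0.05 * n_subjects)`.
#' @return object of class `lesion_matrix`: binary matrix `X`
#'   (subjects x voxels), `voxel_index` (0-based p x 3), `linear_index`
#'   (1-based, into the grid), `dim`, `affine`, `min_coverage`.
#' @export
build_lesion_matrix <- function(masks, min_coverage = 1L) {
  if (min_coverage < 1L) stopf("min_coverage must be >= 1")
  cm <- overlap_map(masks)
  keep <- which(cm$grid >= min_coverage)
  if (length(keep) == 0L)
    stopf("no voxel is lesioned in >= %d subjects", min_coverage)
  X <- vapply(masks, function(m) m$grid[keep], integer(length(keep)))
  X <- t(matrix(X, nrow = length(keep)))
  structure(list(X = X,
                 voxel_index = arrayInd(keep, dim(cm$grid)) - 1L,
                 linear_index = keep,
                 dim = dim(cm$grid), affine = cm$affine,
                 min_coverage = as.integer(min_coverage)),
            class = "lesion_matrix")
}

#' @export
print.lesion_matrix <- function(x, ...) {
  cat(sprintf("<lesion_matrix> %d subjects x %d voxels (coverage >= %d)\n",
              nrow(x$X), ncol(x$X), x$min_coverage))
  invisible(x)
}

design_matrix <- function(X) {
  if (inherits(X, "lesion_matrix")) X$X else as.matrix(X)
}

#' Single-component sparse canonical correlation fit
#'
#' A deliberately simple sparse CCA between a binary lesion matrix and one
#' outcome: the voxel weight vector is the soft-thresholded, nonnegative
#' gradient `X' (y - mean(y))` computed on column-standardised data (each
#' voxel indicator scaled by its standard deviation - the canonical
#' correlation convention; zero-variance columns get zero weight). Without
#' this scaling the gradient is a covariance and the fit systematically
#' favours high-coverage voxels over strongly associated ones. The
#' threshold is chosen so that at most a `sparseness` fraction of weights
#' is nonzero, and the vector is renormalised to unit Euclidean norm.
#' Because the outcome side is a single variable the fixed-point iteration
#' converges immediately; the loop (tolerance 1e-6, at most 100 iterations)
#' is retained so alternative updates can be swapped in. With
#' `sparseness = 1` and an identity design the weights are proportional to
#' the positive part of the centered outcome (standardisation rescales all
#' columns equally there).
#'
#' @param X `lesion_matrix` or numeric matrix (subjects x voxels).
#' @param y binary outcome vector, one per subject, not constant.
#' @param sparseness target fraction of nonzero weights, in `(0, 1]`.
#' @return numeric weight vector (length = voxels), nonnegative, unit norm
#'   unless degenerate; attributes `lambda` (threshold used), `iterations`,
#'   and `degenerate` (TRUE when no voxel has positive association and the
#'   weights are all zero).
#' @export
sccan_fit <- function(X, y, sparseness = 0.1) {
  Xm <- design_matrix(X)
  y <- as.numeric(y)
  if (length(y) != nrow(Xm)) stopf("y length must match rows of X")
  if (stats::var(y) == 0) stopf("constant outcome y")
  if (sparseness <= 0 || sparseness > 1)
    stopf("sparseness must be in (0, 1]")
  ytil <- y - mean(y)
  p <- ncol(Xm)
  k <- max(1L, floor(sparseness * p))
  col_sd <- sqrt(colMeans(Xm^2) - colMeans(Xm)^2)
  w <- rep(0, p)
  lambda <- 0
  iter <- 0L
  repeat {
    iter <- iter + 1L
    g <- drop(crossprod(Xm, ytil))
    g <- ifelse(col_sd > 0, g / col_sd, 0)  # correlation scaling
    g <- pmax(g, 0)                      # nonnegativity
    nz <- sum(g > 0)
    lambda <- if (nz > k) sort(g, decreasing = TRUE)[k + 1L] else 0
    w_new <- pmax(g - lambda, 0)         # soft threshold
    nrm <- sqrt(sum(w_new^2))
    if (nrm > 0) w_new <- w_new / nrm
    if (max(abs(w_new - w)) < 1e-6 || iter >= 100L) { w <- w_new; break }
    w <- w_new
  }
  structure(w, lambda = lambda, iterations = iter,
            degenerate = all(w == 0))
}

# Stratified 75/25 (or holdout_fraction) split; both classes present on both
# sides. Returns list(train, test) of row indices.
stratified_split <- function(y, holdout_fraction) {
  pos <- which(y == 1)
  neg <- which(y == 0)
  if (length(pos) < 2L || length(neg) < 2L)
    stopf("stratified splitting impossible: need >= 2 subjects per class")
  n_test_pos <- min(length(pos) - 1L,
                    max(1L, round(holdout_fraction * length(pos))))
  n_test_neg <- min(length(neg) - 1L,
                    max(1L, round(holdout_fraction * length(neg))))
  test <- c(sample(pos, n_test_pos), sample(neg, n_test_neg))
  list(train = setdiff(seq_along(y), test), test = sort(test))
}

#' Cross-validated sparseness selection
#'
#' Repeats stratified holdout splits (default 75% train / 25% test); for
#' each candidate sparseness the model is fit on the training subjects and
#' the held-out subjects are scored by the raw projection `X_test w`; the
#' Pearson correlation between scores and held-out outcomes is recorded.
#' The sparseness with the highest mean held-out correlation is chosen,
#' ties going to the smaller (sparser) value. The same splits are reused
#' across the grid so candidates face identical data.
#'
#' @inheritParams sccan_fit
#' @param grid candidate sparseness values; default
#'   `c(0.005, 0.01, 0.02, 0.05, 0.1, 0.2)`.
#' @param n_repeats number of repeated splits (default 20; repeats
#'   stabilise the estimate at cohort scale).
#' @param holdout_fraction fraction held out per split (default 0.25).
#' @param seed integer seed; the procedure is deterministic given it.
#' @return list: `chosen_sparseness`, `cv_correlation` (mean held-out
#'   correlation at the chosen value), `table` (mean correlation per grid
#'   value), `n_repeats`, `seed`.
#' @export
select_sparseness <- function(X, y,
                              grid = c(0.005, 0.01, 0.02, 0.05, 0.1, 0.2),
                              n_repeats = 20, holdout_fraction = 0.25,
                              seed = 1) {
  Xm <- design_matrix(X)
  y <- as.numeric(y)
  if (length(grid) == 0L) stopf("empty sparseness grid")
  if (stats::var(y) == 0) stopf("constant outcome y")
  cors <- matrix(NA_real_, nrow = n_repeats, ncol = length(grid))
  with_seed(seed, {
    for (r in seq_len(n_repeats)) {
      sp <- stratified_split(y, holdout_fraction)
      for (j in seq_along(grid)) {
        w <- sccan_fit(Xm[sp$train, , drop = FALSE], y[sp$train], grid[j])
        s <- drop(Xm[sp$test, , drop = FALSE] %*% as.numeric(w))
        cors[r, j] <- if (stats::sd(s) == 0 || stats::sd(y[sp$test]) == 0) 0
                      else stats::cor(s, y[sp$test])
      }
    }
  })
  mean_cor <- colMeans(cors)
  best <- which(mean_cor == max(mean_cor))
  best <- best[which.min(grid[best])]
  list(chosen_sparseness = grid[best], cv_correlation = mean_cor[best],
       table = stats::setNames(mean_cor, grid),
       n_repeats = n_repeats, seed = seed)
}

#' Lesion-symptom mapping (simplified sparse CCA pipeline)
#'
#' Full multivariate lesion-symptom mapping stage: build the lesion matrix,
#' select the sparseness by repeated cross-validation, refit on all
#' subjects, and scatter the voxel weights back onto the grid as a
#' `weighted_map` with its peak world coordinate. Deterministic given
#' `seed`. This is an explicitly simplified stand-in for SCCAN-style
#' mapping (single component, soft thresholding, nonnegative weights);
#' [sccan_fit()] is the swappable core.
#'
#' @param masks list of `lesion_mask`, one per subject, cohort order.
#' @param y binary symptom status vector (not constant).
#' @param min_coverage minimum subjects lesioned per voxel; default
#'   `ceiling(0.05 * length(masks))`.
#' @inheritParams select_sparseness
#' @return object of class `lsm_result`: `map` (`weighted_map` of voxel
#'   weights, unit Euclidean norm over included voxels), `weights`,
#'   `cv_correlation`, `chosen_sparseness`, `peak_world_mm`, `peak_value`,
#'   `degenerate`, `seed`.
#' @export
lsm_map <- function(masks, y, min_coverage = NULL,
                    grid = c(0.005, 0.01, 0.02, 0.05, 0.1, 0.2),
                    n_repeats = 20, holdout_fraction = 0.25, seed = 1) {
  y <- as.integer(y)
  if (length(y) != length(masks))
    stopf("one outcome per mask required")
  if (length(unique(y)) < 2L) stopf("constant outcome y")
  if (is.null(min_coverage)) min_coverage <- ceiling(0.05 * length(masks))
  lm <- build_lesion_matrix(masks, min_coverage)
  sel <- select_sparseness(lm, y, grid = grid, n_repeats = n_repeats,
                           holdout_fraction = holdout_fraction, seed = seed)
  w <- sccan_fit(lm, y, sel$chosen_sparseness)
  g <- array(0, dim = lm$dim)
  g[lm$linear_index] <- as.numeric(w)
  map <- weighted_map(g, lm$affine)
  degenerate <- isTRUE(attr(w, "degenerate"))
  peak <- if (degenerate) list(world_mm = rep(NA_real_, 3), value = 0)
          else peak_coordinate(map)
  structure(list(map = map, weights = as.numeric(w),
                 voxel_index = lm$voxel_index,
                 cv_correlation = sel$cv_correlation,
                 chosen_sparseness = sel$chosen_sparseness,
                 cv_table = sel$table,
                 peak_world_mm = peak$world_mm, peak_value = peak$value,
                 degenerate = degenerate, seed = seed),
            class = "lsm_result")
}

#' @export
print.lsm_result <- function(x, ...) {
  cat(sprintf("<lsm_result> sparseness %.3g, cv correlation %.3f\n",
              x$chosen_sparseness, x$cv_correlation))
  if (x$degenerate) cat("  degenerate fit: all weights zero\n")
  else cat(sprintf("  peak at world mm (%.1f, %.1f, %.1f), weight %.3g\n",
                   x$peak_world_mm[1], x$peak_world_mm[2],
                   x$peak_world_mm[3], x$peak_value))
  invisible(x)
}
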