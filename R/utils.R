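#' @keywords internal
"_PACKAGE"

# Evaluate an expression under a fixed RNG seed, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# 0-based voxel indices (n x 3) -> world mm coordinates (n x 3), NIfTI
# convention: world = affine %*% c(i, j, k, 1) with 0-based i, j, k.
voxel_to_world <- function(affine, idx0) {
  idx0 <- matrix(as.numeric(idx0), ncol = 3)
  h <- cbind(idx0, 1) %*% t(affine)
  h[, 1:3, drop = FALSE]
}

world_to_voxel <- function(affine, world) {
  world <- matrix(as.numeric(world), ncol = 3)
  h <- cbind(world, 1) %*% t(solve(affine))
  h[, 1:3, drop = FALSE]
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
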