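test_that("lesion matrix keeps voxels with sufficient coverage", {
  m <- mask_at(rbind(c(2, 2, 2), c(3, 3, 3)))
  lm3 <- build_lesion_matrix(list(m, m, m), min_coverage = 3)
  expect_equal(ncol(lm3$X), 2L)
  expect_true(all(lm3$X == 1L))
  expect_equal(nrow(lm3$X), 3L)

  # disjoint masks: no voxel reaches coverage 2
  d1 <- mask_at(c(1, 1, 1)); d2 <- mask_at(c(9, 9, 9))
  expect_error(build_lesion_matrix(list(d1, d2), min_coverage = 2),
               "no voxel")

  # column census equals a brute-force count
  set.seed(13)
  masks <- lapply(1:10, function(i) random_mask(8, 0.3))
  counts <- Reduce(`+`, lapply(masks, `[[`, "grid"))
  lm <- build_lesion_matrix(masks, min_coverage = 3)
  expect_equal(ncol(lm$X), sum(counts >= 3))
  expect_equal(colSums(lm$X), unname(counts[counts >= 3]))
})

test_that("sccan_fit recovers a planted causal voxel", {
  pm <- planted_matrix(n = 40, p = 30, causal = 7)
  w <- sccan_fit(pm$X, pm$y, sparseness = 0.1)
  expect_equal(which.max(w), pm$causal)
  # sparseness bound respected: at most floor(0.1 * 30) = 3 nonzero
  expect_lte(sum(w > 0), 3L)
  expect_equal(sum(w^2), 1, tolerance = 1e-12)
})

test_that("sccan_fit closed form at sparseness 1 on an identity design", {
  y <- c(1, 0, 0, 1, 0)
  w <- sccan_fit(diag(5), y, sparseness = 1)
  expected <- pmax(y - mean(y), 0)
  expected <- expected / sqrt(sum(expected^2))
  expect_equal(as.numeric(w), expected, tolerance = 1e-12)
})

test_that("sccan_fit weights are always nonnegative and unit norm", {
  set.seed(23)
  for (i in 1:15) {
    X <- matrix(rbinom(30 * 25, 1, 0.3), 30, 25)
    y <- rbinom(30, 1, 0.5)
    if (var(y) == 0) next
    w <- sccan_fit(X, y, sparseness = runif(1, 0.05, 1))
    expect_true(all(w >= 0))
    if (!attr(w, "degenerate"))
      expect_equal(sum(w^2), 1, tolerance = 1e-10)
  }
  expect_error(sccan_fit(matrix(0:1, 4, 3), rep(1, 4)), "constant")
  expect_error(sccan_fit(matrix(0:1, 4, 3), 0:1), "length")
})

test_that("sparseness selection maximises held-out correlation", {
  # strong planted signal: small sparseness wins and predicts well
  pm <- planted_matrix(n = 60, p = 40, causal = 11, seed = 5)
  set.seed(5)
  y <- pm$y
  flip <- sample(60, 5)                # mild label noise
  y[flip] <- 1 - y[flip]
  sel <- select_sparseness(pm$X, y, grid = c(0.025, 0.5), n_repeats = 10,
                           seed = 2)
  expect_equal(sel$chosen_sparseness, 0.025)
  expect_gt(sel$cv_correlation, 0.5)

  # a one-value grid returns that value
  one <- select_sparseness(pm$X, y, grid = 0.1, n_repeats = 4, seed = 2)
  expect_equal(one$chosen_sparseness, 0.1)

  # pure-noise outcome: mean held-out correlation near zero
  set.seed(8)
  Xn <- matrix(rbinom(80 * 50, 1, 0.3), 80, 50)
  yn <- rep(c(0, 1), 40)
  seln <- select_sparseness(Xn, yn, grid = c(0.05, 0.2), n_repeats = 20,
                            seed = 3)
  expect_lt(abs(seln$cv_correlation), 0.25)

  expect_error(select_sparseness(pm$X, y, grid = numeric(0)), "empty")
  expect_error(select_sparseness(pm$X[1:3, ], c(1, 0, 1),
                                 grid = 0.1), "splitting impossible")
})

test_that("lsm_map is deterministic and localises a causal ROI", {
  ph <- small_phantom()
  sim <- simulate_cohort(small_cohort_spec(n_subjects = 30, beta1 = 0.2,
                                           seed = 7000), ph)
  y <- sim$cohort$status
  expect_equal(sort(unique(y)), c(0L, 1L))  # both classes present
  res1 <- lsm_map(sim$masks, y, n_repeats = 6, seed = 99)
  res2 <- lsm_map(sim$masks, y, n_repeats = 6, seed = 99)
  expect_identical(res1$weights, res2$weights)
  expect_identical(res1$peak_world_mm, res2$peak_world_mm)
  expect_identical(res1$cv_correlation, res2$cv_correlation)

  expect_true(all(res1$weights >= 0))
  expect_equal(sum(res1$weights^2), 1, tolerance = 1e-10)
  expect_equal(dim(res1$map$grid), dim(ph$outflow$grid))
  # the map holds exactly the fitted weights at the matrix voxels
  expect_equal(sum(res1$map$grid^2), 1, tolerance = 1e-10)

  # constant outcomes are rejected
  expect_error(lsm_map(sim$masks, rep(1L, 30)), "constant")
})
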