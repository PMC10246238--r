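test_that("phantom construction invariants hold", {
  ph <- small_phantom()
  expect_gt(volume_mm3(ph$outflow), 0)
  # tube strictly inside the cerebellum
  expect_true(all(ph$cerebellum$grid[ph$outflow$grid == 1L] == 1L))
  # vermis map is a positive bump restricted to the cerebellum
  expect_true(all(ph$vermis_wmap$grid >= 0))
  expect_true(all(ph$vermis_wmap$grid[ph$cerebellum$grid == 0L] == 0))
  expect_gt(max(ph$vermis_wmap$grid), 0)

  expect_error(phantom_spec(outflow_radius_mm = 0), "radius")
  expect_error(phantom_spec(cerebellum_semiaxes_mm = c(100, 26, 22)),
               "exceeds the grid")
  # a tube that pokes out of the cerebellum is rejected at construction
  expect_error(make_phantom(phantom_spec(grid_shape = c(48, 48, 48),
                                         cerebellum_semiaxes_mm = c(20, 17, 14),
                                         outflow_halflength_mm = 20,
                                         outflow_center_mm = c(0, 0))),
               "outside the cerebellum")
})

test_that("slicing the tube at its own tilt gives near-constant mid-span counts", {
  ph <- small_phantom()
  sp <- slice_partition(ph$outflow,
                        angle_deg = ph$spec$outflow_angle_deg)
  counts <- as.integer(sp$bin_counts)
  n <- length(counts)
  mid <- counts[ceiling(n / 4):floor(3 * n / 4)]
  expect_lt(stats::sd(mid) / mean(mid), 0.15)
})

test_that("simulate_lesion is deterministic and respects its envelope", {
  ph <- small_phantom()
  cs <- small_cohort_spec(n_subjects = 6)
  a <- simulate_lesion(cs, ph, subject_seed = 12)
  b <- simulate_lesion(cs, ph, subject_seed = 12)
  expect_identical(a$grid, b$grid)

  for (s in 1:25) {
    m <- simulate_lesion(cs, ph, subject_seed = 100 + s)
    v <- volume_mm3(m)
    # within the spec range, with the 20% clipping allowance
    expect_gte(v, 0.8 * cs$volume_range_mm3[1])
    expect_lte(v, 1.2 * cs$volume_range_mm3[2])
    # and within 20% of this draw's own target
    tgt <- attr(m, "target_volume_mm3")
    expect_gte(v, 0.8 * tgt)
    expect_lte(v, 1.2 * tgt)
    # lesion confined to the cerebellum
    expect_true(all(ph$cerebellum$grid[m$grid == 1L] == 1L))
  }
})

test_that("midline_bias = 1 places every lesion center in the vermis band", {
  ph <- small_phantom()
  cs <- small_cohort_spec(n_subjects = 4, midline_bias = 1)
  for (s in 1:10) {
    m <- simulate_lesion(cs, ph, subject_seed = 400 + s)
    ctr <- attr(m, "center_world_mm")
    expect_lte(abs(ctr[1]), ph$spec$vermis_halfwidth_mm)
  }
})

test_that("mean simulated volume tracks the target-range midpoint", {
  ph <- small_phantom()
  cs <- small_cohort_spec(n_subjects = 4)
  vols <- vapply(1:300, function(s)
    volume_mm3(simulate_lesion(cs, ph, subject_seed = 5000 + s)),
    numeric(1))
  mid <- mean(cs$volume_range_mm3)
  expect_lt(abs(mean(vols) - mid) / mid, 0.15)
})

test_that("cohort generation is deterministic end to end", {
  ph <- small_phantom()
  cs <- small_cohort_spec(n_subjects = 8, seed = 77)
  s1 <- simulate_cohort(cs, ph)
  s2 <- simulate_cohort(cs, ph)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(lapply(s1$masks, `[[`, "grid"),
                   lapply(s2$masks, `[[`, "grid"))
  # table is internally consistent
  expect_equal(s1$cohort$lesion_volume_mm3,
               vapply(s1$masks, volume_mm3, numeric(1)))
  expect_true(all(s1$cohort$status %in% 0:1))
  expect_true(all(s1$cohort$age_years >= 0.4 & s1$cohort$age_years <= 14))
})

test_that("a flat dose-response slope breaks the load-symptom association", {
  ph <- small_phantom()
  # with beta1 = 0 the symptom rate is logistic(beta0) regardless of load;
  # pool subjects over replicates and test independence of load and label
  loads <- labels <- NULL
  for (r in 1:6) {
    cs <- small_cohort_spec(n_subjects = 20, beta1 = 0, beta0 = -1,
                            seed = 300 * r)
    co <- simulate_cohort(cs, ph)$cohort
    loads <- c(loads, co$outflow_load_percent)
    labels <- c(labels, co$status)
  }
  tab <- table(loads > median(loads), labels)
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.01)
})

test_that("a strong positive slope yields higher loads in symptomatic subjects", {
  ph <- small_phantom()
  positive_t <- 0
  for (r in 1:10) {
    cs <- small_cohort_spec(n_subjects = 30, beta1 = 0.2, seed = 500 * r)
    co <- simulate_cohort(cs, ph)$cohort
    if (length(unique(co$status)) < 2) next
    t <- welch_t(co$outflow_load_percent[co$status == 1],
                 co$outflow_load_percent[co$status == 0])$t
    positive_t <- positive_t + (t > 0)
  }
  expect_gte(positive_t, 9)
})
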