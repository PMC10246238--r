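#' Specification of the synthetic cerebellar phantom
#'
#' Geometry of a digital phantom emulating the anatomy the analysis
#' assumes: an ellipsoidal "cerebellum", a compact paired tube standing in
#' for the cerebellar outflow pathway (deep nuclei plus superior cerebellar
#' peduncles), and a smooth midline "vermis" weight bump standing in for an
#' a-priori lesion-symptom map. World coordinates are mm with the origin at
#' the grid center (so midline is x = 0).
#'
#' @param grid_shape integer length-3; default 96^3 voxels, sized so the
#'   cerebellum has a realistic volume (about 190 cm^3) relative to the
#'   default lesion volume range.
#' @param voxel_size_mm isotropic voxel edge, default 1 mm.
#' @param cerebellum_semiaxes_mm ellipsoid semi-axes (x, y, z), default
#'   `c(42, 36, 30)`.
#' @param outflow_radius_mm tube radius, default 3 (> 0).
#' @param outflow_angle_deg tube axis polar angle from the y axis in the
#'   y-z plane, default 17 - so oblique slicing at the same angle is
#'   perpendicular to the tubes.
#' @param outflow_halflength_mm half tube length, default 18.
#' @param outflow_offset_mm lateral (x) offset of each tube from midline,
#'   default 7 (paired left/right tubes).
#' @param outflow_center_mm (y, z) mm position of the tube midpoint,
#'   default `c(12, 8)`: the outflow pathway sits anterosuperiorly in the
#'   cerebellum, away from the posterior-inferior tumor bed where lesions
#'   concentrate.
#' @param vermis_halfwidth_mm half-width of the midline band, default 7;
#'   also the x standard deviation of the vermis weight bump.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96L, 96L, 96L),
                         voxel_size_mm = 1,
                         cerebellum_semiaxes_mm = c(42, 36, 30),
                         outflow_radius_mm = 3,
                         outflow_angle_deg = 17,
                         outflow_halflength_mm = 18,
                         outflow_offset_mm = 7,
                         outflow_center_mm = c(12, 8),
                         vermis_halfwidth_mm = 7) {
  if (outflow_radius_mm <= 0) stopf("tube radius must be > 0")
  if (any(grid_shape < 8)) stopf("grid too small")
  half_extent <- (grid_shape - 1) / 2 * voxel_size_mm
  if (any(cerebellum_semiaxes_mm >= half_extent))
    stopf("cerebellum exceeds the grid")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm,
                 cerebellum_semiaxes_mm = cerebellum_semiaxes_mm,
                 outflow_radius_mm = outflow_radius_mm,
                 outflow_angle_deg = outflow_angle_deg,
                 outflow_halflength_mm = outflow_halflength_mm,
                 outflow_offset_mm = outflow_offset_mm,
                 outflow_center_mm = outflow_center_mm,
                 vermis_halfwidth_mm = vermis_halfwidth_mm),
            class = "phantom_spec")
}

phantom_affine <- function(spec) {
  a <- diag(c(rep(spec$voxel_size_mm, 3), 1))
  a[1:3, 4] <- -(spec$grid_shape - 1) / 2 * spec$voxel_size_mm
  a
}

# World-coordinate component arrays for a phantom grid.
phantom_world <- function(spec) {
  d <- spec$grid_shape
  ax <- ((0:(d[1] - 1)) - (d[1] - 1) / 2) * spec$voxel_size_mm
  ay <- ((0:(d[2] - 1)) - (d[2] - 1) / 2) * spec$voxel_size_mm
  az <- ((0:(d[3] - 1)) - (d[3] - 1) / 2) * spec$voxel_size_mm
  list(x = array(ax, dim = d),
       y = array(rep(ay, each = d[1]), dim = d),
       z = array(rep(az, each = d[1] * d[2]), dim = d))
}

#' Build the synthetic phantom volumes
#'
#' Deterministic construction of the phantom defined by a [phantom_spec()]:
#' the cerebellum ellipsoid mask, the paired outflow tubes (validated to
#' lie inside the cerebellum), and the vermis weighted map - a smooth
#' Gaussian bump centered on the midline band, restricted to the
#' cerebellum. Slicing the tube mask at its own tilt angle gives
#' near-constant per-slice voxel counts over the tube's middle span, which
#' is what makes the oblique slice-load statistic geometrically meaningful
#' on this phantom.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `cerebellum` (`lesion_mask`), `outflow`
#'   (`lesion_mask`), `vermis_wmap` (`weighted_map`) and `spec`.
#' @examples
#' ph <- make_phantom(phantom_spec(grid_shape = c(32, 32, 32),
#'                                 cerebellum_semiaxes_mm = c(14, 12, 10),
#'                                 outflow_halflength_mm = 8,
#'                                 outflow_offset_mm = 4,
#'                                 outflow_radius_mm = 2,
#'                                 outflow_center_mm = c(0, 0)))
#' volume_mm3(ph$outflow)
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  w <- phantom_world(spec)
  s <- spec$cerebellum_semiaxes_mm
  cereb <- (w$x / s[1])^2 + (w$y / s[2])^2 + (w$z / s[3])^2 <= 1
  theta <- spec$outflow_angle_deg * pi / 180
  u <- c(cos(theta), sin(theta))          # tube axis in the y-z plane
  y0 <- spec$outflow_center_mm[1]
  z0 <- spec$outflow_center_mm[2]
  tube <- array(FALSE, dim = spec$grid_shape)
  for (cx in c(-1, 1) * spec$outflow_offset_mm) {
    t_ax <- (w$y - y0) * u[1] + (w$z - z0) * u[2]  # position along the axis
    d2 <- (w$x - cx)^2 + (w$y - y0 - t_ax * u[1])^2 +
          (w$z - z0 - t_ax * u[2])^2
    tube <- tube | (d2 <= spec$outflow_radius_mm^2 &
                    abs(t_ax) <= spec$outflow_halflength_mm)
  }
  if (any(tube & !cereb))
    stopf("outflow tube extends outside the cerebellum; shrink the tube or enlarge the cerebellum")
  if (!any(tube)) stopf("outflow tube is empty on this grid")
  aff <- phantom_affine(spec)
  hw <- spec$vermis_halfwidth_mm
  bump <- exp(-0.5 * (w$x / hw)^2 - 0.5 * (w$y^2 + w$z^2) / (2 * hw)^2)
  bump[!cereb] <- 0
  list(cerebellum = lesion_mask(array(as.integer(cereb),
                                      dim = spec$grid_shape), aff),
       outflow = lesion_mask(array(as.integer(tube),
                                   dim = spec$grid_shape), aff),
       vermis_wmap = weighted_map(bump, aff),
       spec = spec)
}

#' Specification of a synthetic lesion cohort
#'
#' Statistical structure of a simulated resection-cavity cohort: ellipsoidal
#' lesions with volumes drawn uniformly from `volume_range_mm3`, centers
#' biased toward the midline (vermis) band with probability `midline_bias`,
#' and binary symptom labels drawn from a logistic model of the true
#' outflow lesion load:
#' `P(symptom) = plogis(beta0 + beta1 * load_percent)`, optionally
#' corrupted by flipping each label with probability `label_noise`.
#'
#' Defaults emulate a pediatric posterior-fossa resection cohort: n = 56
#' subjects, lesion volumes 1,000-30,000 mm^3, and `beta0 = -3`,
#' `beta1 = 0.06` per load percent, which yields cohort symptom rates near
#' 18% under the default phantom (calibrated by simulation).
#'
#' @param n_subjects cohort size (>= 4), default 56.
#' @param volume_range_mm3 lesion target-volume range, default
#'   `c(1000, 30000)`.
#' @param midline_bias probability a lesion center lies within the vermis
#'   band, default 0.7.
#' @param bed_limit_mm named-free (y, z) upper limits for lesion centers,
#'   default `c(-6, -6)`: resection cavities concentrate in the
#'   posterior-inferior cerebellum (the tumor bed), away from the
#'   anterosuperior outflow pathway, which is what produces the skewed
#'   lesion-load distribution (many spared ROIs, a tail of heavy loads)
#'   the dose-response model assumes.
#' @param beta0,beta1 logistic intercept and slope (per load percent),
#'   defaults -3 and 0.06.
#' @param label_noise probability each symptom label is flipped after
#'   generation, default 0.
#' @param age_mean_years,age_sd_years cohort age distribution (truncated
#'   normal on 0.4-14 years), defaults 6.2 and 3.7.
#' @param seed master seed; per-subject seeds are derived as
#'   `seed + subject_index` (lesions) and `seed + n_subjects + subject_index`
#'   (labels and ages), so single subjects can be regenerated.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 56L,
                        volume_range_mm3 = c(1000, 30000),
                        midline_bias = 0.7,
                        bed_limit_mm = c(-6, -6),
                        beta0 = -3, beta1 = 0.06,
                        label_noise = 0,
                        age_mean_years = 6.2, age_sd_years = 3.7,
                        seed = 1L) {
  if (n_subjects < 4L) stopf("n_subjects must be >= 4")
  if (any(volume_range_mm3 <= 0) || diff(volume_range_mm3) < 0)
    stopf("invalid volume range")
  if (midline_bias < 0 || midline_bias > 1)
    stopf("midline_bias must be in [0, 1]")
  if (!is.finite(beta1)) stopf("beta1 must be finite")
  if (label_noise < 0 || label_noise > 0.5)
    stopf("label_noise must be in [0, 0.5]")
  structure(list(n_subjects = as.integer(n_subjects),
                 volume_range_mm3 = volume_range_mm3,
                 midline_bias = midline_bias,
                 bed_limit_mm = bed_limit_mm,
                 beta0 = beta0, beta1 = beta1,
                 label_noise = label_noise,
                 age_mean_years = age_mean_years,
                 age_sd_years = age_sd_years,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate one lesion mask
#'
#' Draws a random ellipsoidal lesion: a target volume uniform over the spec
#' range, random axis anisotropy (ratios 0.6-1.4) scaled analytically to
#' the target volume, and a center voxel sampled inside the tumor bed (the
#' posterior-inferior cerebellum, see [cohort_spec()]) - within the midline
#' band with probability `midline_bias`. The rasterized ellipsoid is
#' intersected with the cerebellum; the target volume is held fixed while
#' center and shape are redrawn (up to 100 attempts) until the final mask
#' volume lies within 20% of the target, so boundary clipping can neither
#' push a lesion outside the spec's volume envelope nor bias the cohort
#' volume distribution toward small lesions.
#'
#' @param spec a [cohort_spec()].
#' @param phantom output of [make_phantom()].
#' @param subject_seed integer; identical seeds give identical masks.
#' @return `lesion_mask` on the phantom grid, with attributes
#'   `target_volume_mm3` and `center_world_mm`.
#' @export
simulate_lesion <- function(spec, phantom, subject_seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  w <- phantom_world(phantom$spec)
  cereb <- phantom$cerebellum$grid == 1L
  bed <- cereb & w$y <= spec$bed_limit_mm[1] & w$z <= spec$bed_limit_mm[2]
  inside <- which(bed)
  band <- which(bed & abs(w$x) <= phantom$spec$vermis_halfwidth_mm)
  if (length(inside) == 0L || length(band) == 0L)
    stopf("tumor bed is empty: bed_limit_mm excludes the whole cerebellum")
  vox_vol <- prod(voxel_size(phantom$cerebellum))
  with_seed(subject_seed, {
    target <- stats::runif(1, spec$volume_range_mm3[1],
                           spec$volume_range_mm3[2])
    for (attempt in seq_len(100L)) {
      ratio <- stats::runif(3, 0.6, 1.4)
      base <- (3 * target / (4 * pi * prod(ratio)))^(1 / 3)
      ax <- base * ratio
      pool <- if (stats::runif(1) < spec$midline_bias) band else inside
      ctr_lin <- pool[sample.int(length(pool), 1L)]
      cx <- w$x[ctr_lin]; cy <- w$y[ctr_lin]; cz <- w$z[ctr_lin]
      les <- ((w$x - cx) / ax[1])^2 + ((w$y - cy) / ax[2])^2 +
             ((w$z - cz) / ax[3])^2 <= 1
      les <- les & cereb
      vol <- sum(les) * vox_vol
      if (vol >= 0.8 * target && vol <= 1.2 * target) {
        m <- lesion_mask(array(as.integer(les), dim = dim(cereb)),
                         phantom$cerebellum$affine)
        attr(m, "target_volume_mm3") <- target
        attr(m, "center_world_mm") <- c(cx, cy, cz)
        return(m)
      }
    }
    stopf("could not place a lesion within the volume envelope after 100 attempts")
  })
}

#' Simulate a full cohort of lesions and symptom labels
#'
#' For each subject: a lesion via [simulate_lesion()]; its true outflow
#' lesion load at the phantom's tube tilt angle; a symptom probability from
#' the logistic dose-response model; a Bernoulli label (optionally flipped
#' with probability `label_noise`); an age from a truncated normal. The
#' returned table records the ground truth so downstream stages can be
#' validated against it.
#'
#' @inheritParams simulate_lesion
#' @return list with `masks` (list of `lesion_mask`), `cohort`
#'   (data.frame: subject_id, status, age_years, lesion_volume_mm3,
#'   outflow_load_percent, weighted_load, p_symptom), and `phantom`.
#' @examples
#' ph <- make_phantom(phantom_spec(grid_shape = c(32, 32, 32),
#'                                 cerebellum_semiaxes_mm = c(14, 12, 10),
#'                                 outflow_halflength_mm = 8,
#'                                 outflow_offset_mm = 4,
#'                                 outflow_radius_mm = 2,
#'                                 outflow_center_mm = c(0, 0)))
#' cs <- cohort_spec(n_subjects = 6, volume_range_mm3 = c(200, 1500),
#'                   bed_limit_mm = c(0, 0))
#' sim <- simulate_cohort(cs, ph)
#' head(sim$cohort)
#' @export
simulate_cohort <- function(spec, phantom) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  masks <- vector("list", n)
  load <- wload <- p <- status <- age <- numeric(n)
  for (i in seq_len(n)) {
    masks[[i]] <- simulate_lesion(spec, phantom, spec$seed + i)
    load[i] <- outflow_lesion_load(masks[[i]], phantom$outflow,
                                   angle_deg = phantom$spec$outflow_angle_deg)$load_percent
    wload[i] <- weighted_map_lesion_load(masks[[i]],
                                         phantom$vermis_wmap)$normalized_load
    p[i] <- stats::plogis(spec$beta0 + spec$beta1 * load[i])
    with_seed(spec$seed + n + i, {
      status[i] <- stats::rbinom(1, 1, p[i])
      if (spec$label_noise > 0 &&
          stats::runif(1) < spec$label_noise)
        status[i] <- 1 - status[i]
      repeat {
        age[i] <- stats::rnorm(1, spec$age_mean_years, spec$age_sd_years)
        if (age[i] >= 0.4 && age[i] <= 14) break
      }
    })
  }
  cohort <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    status = as.integer(status),
    age_years = round(age, 2),
    lesion_volume_mm3 = vapply(masks, volume_mm3, numeric(1)),
    outflow_load_percent = load,
    weighted_load = wload,
    p_symptom = p)
  list(masks = masks, cohort = cohort, phantom = phantom)
}

#' Write a simulated cohort to disk
#'
#' Writes the phantom ROIs, per-subject lesion masks (NIfTI-1) and the
#' cohort table (CSV) in the layout [run_study()] consumes.
#'
#' @param sim output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(file.path(dir, "lesions"), recursive = TRUE,
             showWarnings = FALSE)
  write_volume(sim$phantom$outflow, file.path(dir, "outflow_roi.nii.gz"))
  write_volume(sim$phantom$cerebellum, file.path(dir, "cerebellum.nii.gz"))
  write_volume(sim$phantom$vermis_wmap, file.path(dir, "lsm_prior.nii.gz"))
  for (i in seq_along(sim$masks))
    write_volume(sim$masks[[i]],
                 file.path(dir, "lesions",
                           paste0(sim$cohort$subject_id[i], ".nii.gz")))
  utils::write.csv(sim$cohort, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  invisible(dir)
}
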