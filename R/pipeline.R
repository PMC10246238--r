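#' Study configuration
#'
#' Bundles every input path and parameter of the end-to-end analysis. All
#' referenced paths are checked at run time by [run_study()]. The defaults
#' encode the study conventions: 17 degree oblique 1 mm slices for the
#' outflow lesion load, a one-tailed symptomatic > asymptomatic hypothesis
#' for the load comparisons, and the standard sparseness grid for the
#' lesion-symptom mapping stage.
#'
#' @param lesion_dir directory of per-subject lesion masks named
#'   `<subject_id>.nii.gz` (or `.nii`).
#' @param roi_path outflow-pathway ROI mask (NIfTI-1).
#' @param weighted_map_path optional a-priori lesion-symptom map (NIfTI-1);
#'   `NULL` skips the weighted-load analysis.
#' @param cohort_csv cohort table with at least `subject_id`, `status`
#'   (0/1), and optionally `age_years`, `lesion_volume_mm3`.
#' @param angle_deg,bin_width_mm slicing geometry; defaults 17 and 1.
#' @param min_coverage minimum per-voxel lesion coverage for the mapping
#'   stage; `NULL` means `ceiling(0.05 * n)`.
#' @param sparseness_grid,n_repeats,holdout_fraction cross-validation
#'   settings for [lsm_map()].
#' @param rate_edges bin edges for the dose-response table.
#' @param seed integer seed for the mapping stage.
#' @param output_dir where [run_study()] writes its outputs.
#' @return object of class `study_config`.
#' @export
study_config <- function(lesion_dir, roi_path, weighted_map_path = NULL,
                         cohort_csv, angle_deg = 17, bin_width_mm = 1,
                         min_coverage = NULL,
                         sparseness_grid = c(0.005, 0.01, 0.02, 0.05, 0.1, 0.2),
                         n_repeats = 20, holdout_fraction = 0.25,
                         rate_edges = c(0, 1, 25, 50, 75, 100),
                         seed = 1L, output_dir = tempfile("study_")) {
  structure(list(lesion_dir = lesion_dir, roi_path = roi_path,
                 weighted_map_path = weighted_map_path,
                 cohort_csv = cohort_csv, angle_deg = angle_deg,
                 bin_width_mm = bin_width_mm, min_coverage = min_coverage,
                 sparseness_grid = sparseness_grid, n_repeats = n_repeats,
                 holdout_fraction = holdout_fraction,
                 rate_edges = rate_edges, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "study_config")
}

check_config <- function(config) {
  stopifnot(inherits(config, "study_config"))
  for (p in c(config$lesion_dir, config$roi_path, config$cohort_csv,
              config$weighted_map_path))
    if (!file.exists(p)) stopf("config path does not exist: %s", p)
  if (config$angle_deg < 0 || config$angle_deg >= 90)
    stopf("angle_deg out of range")
  if (config$bin_width_mm <= 0) stopf("bin_width_mm must be > 0")
  invisible(TRUE)
}

stage_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the end-to-end lesion-location study analysis
#'
#' Orchestrates the full analysis from a [study_config()]: per-subject
#' outflow and weighted-map lesion loads; group summaries and Welch t-tests
#' (lesion loads one-tailed symptomatic > asymptomatic; age and lesion
#' volume two-tailed, reported alongside); symptom rate and rate by load
#' bin; cohort overlap maps, the proportional subtraction map and their
#' peaks; and the lesion-symptom mapping stage. All intermediate volumes
#' and a machine-readable report are written to `config$output_dir`. Every
#' statistic in the report is recomputable from the per-subject table also
#' written there; the run is deterministic given the config seed.
#'
#' @param config a [study_config()].
#' @return object of class `study_report` (also written as `report.json`),
#'   invisibly.
#' @export
run_study <- function(config) {
  check_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- with_stage("cohort", {
    ct <- utils::read.csv(config$cohort_csv, stringsAsFactors = FALSE)
    if (!all(c("subject_id", "status") %in% names(ct)))
      stopf("cohort CSV needs subject_id and status columns")
    if (!all(ct$status %in% c(0L, 1L))) stopf("status must be binary")
    if (sum(ct$status == 1) < 2L || sum(ct$status == 0) < 2L)
      stopf("need >= 2 subjects per group")
    ct
  })
  stage_msg("cohort", "%d subjects, %d symptomatic", nrow(cohort),
            sum(cohort$status))

  roi <- with_stage("inputs", read_mask(config$roi_path))
  wmap <- if (!is.null(config$weighted_map_path))
    with_stage("inputs", read_weighted_map(config$weighted_map_path))
  masks <- with_stage("inputs", {
    lapply(cohort$subject_id, function(id) {
      f <- file.path(config$lesion_dir, paste0(id, c(".nii.gz", ".nii")))
      f <- f[file.exists(f)]
      if (length(f) == 0L) stopf("no lesion mask for subject %s", id)
      read_mask(f[1])
    })
  })

  loads <- with_stage("lesion_load", {
    cohort$outflow_load_percent <- vapply(masks, function(m)
      outflow_lesion_load(m, roi, config$angle_deg,
                          config$bin_width_mm)$load_percent, numeric(1))
    if (!is.null(wmap))
      cohort$weighted_load <- vapply(masks, function(m)
        weighted_map_lesion_load(m, wmap)$normalized_load, numeric(1))
    cohort
  })
  cohort <- loads
  stage_msg("lesion_load", "outflow load mean %.1f%%",
            mean(cohort$outflow_load_percent))

  pos <- cohort$status == 1
  tests <- with_stage("group_stats", {
    out <- list(outflow_load = welch_t(cohort$outflow_load_percent[pos],
                                       cohort$outflow_load_percent[!pos],
                                       alternative = "greater"))
    if (!is.null(wmap))
      out$weighted_load <- welch_t(cohort$weighted_load[pos],
                                   cohort$weighted_load[!pos],
                                   alternative = "greater")
    if ("age_years" %in% names(cohort))
      out$age <- welch_t(cohort$age_years[pos], cohort$age_years[!pos],
                         alternative = "two_sided")
    if ("lesion_volume_mm3" %in% names(cohort))
      out$lesion_volume <- welch_t(cohort$lesion_volume_mm3[pos],
                                   cohort$lesion_volume_mm3[!pos],
                                   alternative = "two_sided")
    out
  })
  rate <- cms_rate(cohort$status)
  rate_bins <- rate_by_load_bin(cohort$outflow_load_percent, cohort$status,
                                config$rate_edges)
  stage_msg("group_stats", "rate %.1f%%, outflow t(%d)=%.2f p=%.3g",
            100 * rate$rate, tests$outflow_load$df_report,
            tests$outflow_load$t, tests$outflow_load$p_one_tailed)

  maps <- with_stage("maps", {
    all_map <- overlap_map(masks)
    pos_map <- overlap_map(masks[pos])
    neg_map <- overlap_map(masks[!pos])
    sub_map <- proportional_subtraction(masks[pos], masks[!pos])
    write_volume(all_map, file.path(config$output_dir, "overlap_all.nii.gz"))
    write_volume(pos_map, file.path(config$output_dir, "overlap_pos.nii.gz"))
    write_volume(neg_map, file.path(config$output_dir, "overlap_neg.nii.gz"))
    write_volume(sub_map, file.path(config$output_dir, "subtraction.nii.gz"))
    list(peaks = list(all = peak_coordinate(all_map),
                      pos = peak_coordinate(pos_map),
                      neg = peak_coordinate(neg_map),
                      subtraction = peak_coordinate(sub_map)))
  })

  lsm <- with_stage("lsm", {
    res <- lsm_map(masks, cohort$status,
                   min_coverage = config$min_coverage,
                   grid = config$sparseness_grid,
                   n_repeats = config$n_repeats,
                   holdout_fraction = config$holdout_fraction,
                   seed = config$seed)
    write_volume(res$map, file.path(config$output_dir, "lsm_map.nii.gz"))
    res
  })
  stage_msg("lsm", "sparseness %.3g, cv correlation %.3f",
            lsm$chosen_sparseness, lsm$cv_correlation)

  utils::write.csv(cohort,
                   file.path(config$output_dir, "cohort_with_loads.csv"),
                   row.names = FALSE)

  cfg_json <- file.path(config$output_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_json, auto_unbox = TRUE,
                       null = "null", digits = NA)
  report <- structure(list(
    version = as.character(utils::packageVersion("lesionload")),
    config = unclass(config),
    config_hash = unname(tools::md5sum(cfg_json)),
    n_subjects = nrow(cohort),
    cms_rate = rate,
    group_summaries = list(
      outflow_load = list(
        pos = unclass(group_summary(cohort$outflow_load_percent[pos])),
        neg = unclass(group_summary(cohort$outflow_load_percent[!pos])))),
    tests = lapply(tests, function(t)
      t[c("t", "df_exact", "df_report", "p_one_tailed", "p_two_tailed",
          "cohens_d", "alternative")]),
    rate_by_bin = rate_bins,
    map_peaks = maps$peaks,
    lsm = list(chosen_sparseness = lsm$chosen_sparseness,
               cv_correlation = lsm$cv_correlation,
               peak_world_mm = lsm$peak_world_mm,
               degenerate = lsm$degenerate,
               seed = lsm$seed),
    per_subject = cohort), class = "study_report")
  jsonlite::write_json(prune_report(report),
                       file.path(config$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  invisible(report)
}

# Drop non-serialisable bits (classed objects already reduced upstream).
prune_report <- function(report) {
  r <- unclass(report)
  r$rate_by_bin <- as.data.frame(r$rate_by_bin)
  r
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> n=%d, CMS rate %.1f%%\n", x$n_subjects,
              100 * x$cms_rate$rate))
  t <- x$tests$outflow_load
  cat(sprintf("  outflow load: t(%d)=%.2f, p(one-tailed)=%.3g, d=%.2f\n",
              t$df_report, t$t, t$p_one_tailed, t$cohens_d))
  if (!is.null(x$tests$weighted_load)) {
    t <- x$tests$weighted_load
    cat(sprintf("  weighted load: t(%d)=%.2f, p(one-tailed)=%.3g, d=%.2f\n",
                t$df_report, t$t, t$p_one_tailed, t$cohens_d))
  }
  cat(sprintf("  lsm: sparseness %.3g, cv correlation %.3f\n",
              x$lsm$chosen_sparseness, x$lsm$cv_correlation))
  invisible(x)
}
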