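# End-to-end orchestration: validate a run configuration, then
# simulate/load -> register -> quantify -> cohort statistics -> frequency
# map, with logging, a run manifest and deterministic seeding.

default_config <- function() {
  list(
    cohort_dir = NULL,
    template_tensor = NULL,     # default: <cohort_dir>/template_tensor.nii.gz
    output_dir = NULL,
    seed = 1L,
    fa_min = 0,
    eps_mm = 0.1,
    weighting = "count",
    bins = 9L,                  # fixed 9 x 10 degrees
    parallel_max = 20,
    perpendicular_min = 70,
    registration = list(levels = 1L, control_spacing_mm = 8, lambda = 0.01,
                        max_iter = 50, tol = 1e-5, dmax_mm = 10),
    mode = list(mask_to_mask = TRUE, reorient_tensors = TRUE,
                pooled = FALSE),
    rate = "specific",
    alpha = 0.05
  )
}

check_known_keys <- function(raw, defaults, where = "config") {
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stop_growthtrack("growthtrack_config_error",
                     "unknown %s key: '%s'", where, unknown[1])
}

#' Validate a run configuration
#'
#' Fills defaults (9 bins of 10 degrees, parallel below 20 degrees,
#' perpendicular above 70 degrees, `fa_min` 0, count weighting), enforces
#' invariants, and rejects unknown keys by name.
#'
#' @param raw a named list, or the path of a YAML document.
#' @return A validated `run_config` list.
#' @export
validate_config <- function(raw = list()) {
  if (is.character(raw)) {
    if (!file.exists(raw))
      stop_growthtrack("growthtrack_config_error",
                       "config file not found: '%s'", raw)
    raw <- yaml::read_yaml(raw)
    if (is.null(raw)) raw <- list()
  }
  if (!is.list(raw))
    stop_growthtrack("growthtrack_config_error", "config must be a mapping")
  defaults <- default_config()
  check_known_keys(raw, defaults)
  if (!is.null(raw$registration))
    check_known_keys(raw$registration, defaults$registration, "registration")
  if (!is.null(raw$mode))
    check_known_keys(raw$mode, defaults$mode, "mode")
  cfg <- modifyList(defaults, raw)
  if (!identical(as.integer(cfg$bins), 9L))
    stop_growthtrack("growthtrack_config_error",
                     "the bin scheme is fixed at 9 bins of 10 degrees")
  if (!(cfg$parallel_max > 0 && cfg$parallel_max <= cfg$perpendicular_min &&
        cfg$perpendicular_min < 90))
    stop_growthtrack("growthtrack_config_error",
      "thresholds must satisfy 0 < parallel_max <= perpendicular_min < 90")
  if (!cfg$weighting %in% c("count", "magnitude"))
    stop_growthtrack("growthtrack_config_error",
                     "weighting must be 'count' or 'magnitude'")
  if (cfg$fa_min < 0 || cfg$fa_min > 1)
    stop_growthtrack("growthtrack_config_error", "fa_min must lie in [0, 1]")
  if (cfg$eps_mm < 0)
    stop_growthtrack("growthtrack_config_error", "eps_mm must be >= 0")
  if (!cfg$rate %in% c("specific", "linear"))
    stop_growthtrack("growthtrack_config_error",
                     "rate must be 'specific' or 'linear'")
  class(cfg) <- "run_config"
  cfg
}

log_line <- function(con, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

reg_params_from_config <- function(cfg) {
  r <- cfg$registration
  registration_params(levels = r$levels,
                      control_spacing_mm = r$control_spacing_mm,
                      lambda = r$lambda, max_iter = r$max_iter, tol = r$tol,
                      dmax_mm = r$dmax_mm,
                      metric = if (cfg$mode$mask_to_mask) "ssd_distance"
                               else "ssd_image_excluded")
}

#' Run the full pipeline over a cohort directory
#'
#' For every patient subdirectory: read the two masks, estimate the growth
#' deformation field by deformable registration, quantify the
#' growth-to-fiber angle histogram against the template principal-direction
#' map, and collect volumes and growth rate.  Then write the per-patient
#' results CSV, the cohort summary JSON, the tumor frequency map, a run log
#' and a manifest with hashes of every output.  Per-patient failures are
#' logged and the patient is excluded with a reason; fewer than 2 evaluable
#' patients aborts the run.
#'
#' @param config a `run_config` from [validate_config] (or a raw list /
#'   YAML path, validated on the fly).
#' @return The `run_manifest` list, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  if (is.null(cfg$cohort_dir) || !dir.exists(cfg$cohort_dir))
    stop_growthtrack("growthtrack_config_error",
                     "cohort_dir missing or not a directory")
  template_path <- cfg$template_tensor %||%
    file.path(cfg$cohort_dir, "template_tensor.nii.gz")
  if (!file.exists(template_path))
    stop_growthtrack("growthtrack_config_error",
                     "template tensor not found: '%s'", template_path)
  if (is.null(cfg$output_dir))
    stop_growthtrack("growthtrack_config_error", "output_dir is required")
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(cfg$output_dir, "run.log"), open = "wt")
  on.exit(close(logf))
  t_all <- proc.time()[["elapsed"]]

  meta_path <- file.path(cfg$cohort_dir, "metadata.csv")
  meta <- if (file.exists(meta_path))
    read.csv(meta_path, stringsAsFactors = FALSE) else NULL
  patient_dirs <- list.dirs(cfg$cohort_dir, recursive = FALSE)
  patient_dirs <- patient_dirs[file.exists(file.path(patient_dirs,
                                                     "t1_mask.nii.gz"))]
  if (!is.null(meta))
    patient_dirs <- patient_dirs[basename(patient_dirs) %in% meta$patient_id]
  log_line(logf, "cohort '%s': %d patients", cfg$cohort_dir,
           length(patient_dirs))

  tensors <- read_volume(template_path, "tensor")
  dirs <- principal_direction_map(tensors, fa_min = cfg$fa_min)
  log_line(logf, "direction field: %d/%d valid voxels (excluded: %s)",
           sum(dirs$valid), length(dirs$valid),
           paste(names(dirs$exclusions), dirs$exclusions, sep = "=",
                 collapse = ", "))

  rp <- reg_params_from_config(cfg)
  results <- list()
  failures <- list()
  t2_masks <- list()
  stage_times <- c(register = 0, quantify = 0)
  for (pd in patient_dirs) {
    pid <- basename(pd)
    res <- tryCatch({
      t1 <- read_volume(file.path(pd, "t1_mask.nii.gz"), "mask")
      t2 <- read_volume(file.path(pd, "t2_mask.nii.gz"), "mask")
      mi <- fi <- NULL
      if (!cfg$mode$mask_to_mask) {
        mi <- read_volume(file.path(pd, "t1_img.nii.gz"), "image")
        fi <- read_volume(file.path(pd, "t2_img.nii.gz"), "image")
      }
      t0 <- proc.time()[["elapsed"]]
      def <- nonlinear_register_masks(t1, t2, rp, moving_image = mi,
                                      fixed_image = fi)
      stage_times["register"] <- stage_times["register"] +
        proc.time()[["elapsed"]] - t0
      row <- if (!is.null(meta)) meta[meta$patient_id == pid, ] else NULL
      t0 <- proc.time()[["elapsed"]]
      pr <- quantify_patient(
        t1, t2, def, dirs, patient_id = pid,
        interval_days = if (!is.null(row) && nrow(row)) row$interval_days else 1,
        mgmt = if (!is.null(row) && nrow(row)) row$mgmt else "unknown",
        eps_mm = cfg$eps_mm, weighting = cfg$weighting,
        parallel_max = cfg$parallel_max,
        perpendicular_min = cfg$perpendicular_min, rate = cfg$rate)
      stage_times["quantify"] <- stage_times["quantify"] +
        proc.time()[["elapsed"]] - t0
      t2_masks[[pid]] <- t2
      log_line(logf,
               "%s: dice %.3f, %d voxels, parallel %.3f, perpendicular %.3f (excluded: %s)",
               pid, attr(def, "dice"), pr$histogram$n_voxels,
               pr$histogram$parallel_fraction,
               pr$histogram$perpendicular_fraction,
               paste(names(pr$exclusions), pr$exclusions, sep = "=",
                     collapse = ", "))
      pr
    }, error = function(e) {
      log_line(logf, "%s: EXCLUDED (%s)", pid, conditionMessage(e))
      failures[[pid]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(res)) results[[pid]] <- res
  }
  if (length(results) < 2)
    stop_growthtrack("growthtrack_cohort_too_small",
                     "fewer than 2 evaluable patients (%d)", length(results))

  csv_path <- file.path(cfg$output_dir, "patient_results.csv")
  write_results_table(results, csv_path)
  summary <- summarize_cohort(results, alpha = cfg$alpha,
                              pooled = cfg$mode$pooled)
  sum_path <- file.path(cfg$output_dir, "cohort_summary.json")
  jsonlite::write_json(summary_to_json(summary), sum_path,
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  fmap <- frequency_map(unname(t2_masks))
  fmap_path <- file.path(cfg$output_dir, "tumor_frequency_map.nii.gz")
  write_volume(fmap, fmap_path)

  outputs <- c(csv_path, sum_path, fmap_path)
  manifest <- list(
    config = unclass(cfg),
    n_evaluable = length(results),
    excluded = failures,
    outputs = lapply(setNames(outputs, basename(outputs)), function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))),
    stage_seconds = as.list(round(stage_times, 2)),
    total_seconds = round(proc.time()[["elapsed"]] - t_all, 2),
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("growthtrack"))
  )
  man_path <- file.path(cfg$output_dir, "run_manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  log_line(logf, "done: %d evaluable, %d excluded, %.1f s",
           length(results), length(failures), manifest$total_seconds)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

summary_to_json <- function(s) {
  list(
    n = s$n,
    bin_means = as.data.frame(s$bin_means),
    pooled_bins = s$pooled_bins,
    parallel = s$parallel,
    perpendicular = s$perpendicular,
    paired_test = s$paired_test,
    normality = s$normality,
    mgmt_anova = s$mgmt_anova,
    parallel_preference = s$parallel_preference,
    alpha = s$alpha,
    notes = s$notes
  )
}
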