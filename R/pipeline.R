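#' Simulate the UVC and align its clock to the patient's
#'
#' Runs the untreated-virtual-control simulation from an initial condition
#' built by [build_initial_condition()] and re-labels the simulation clock
#' so that the moment the simulated T1Gd SE radius regrows to the *observed*
#' (pre-erosion) pre-treatment radius coincides with the observation day.
#' Without this alignment the perimeter erosion would shift every Days
#' Gained score by roughly `mm_removed / velocity` days. The simulation is
#' automatically extended until the aligned curve covers `t_post`.
#'
#' @param initial [cell_density_field()] from [build_initial_condition()].
#' @param params [kinetic_parameters()].
#' @param r_obs Observed (uneroded) T1Gd SE radius in mm at the observation
#'   day.
#' @param obs_day Day of the observation the initial condition was built
#'   from (patient clock).
#' @param t_post Post-treatment day the curve must reach (patient clock).
#' @param thresholds [detection_thresholds()].
#' @param sample_interval Days between curve samples.
#' @param dt Optional explicit time step.
#' @return A `growth_curve` on the patient clock, spanning exactly
#'   `[obs_day, t_post]` (endpoints included via linear interpolation of the
#'   sampled curve), with attribute `alignment_shift` (days of regrowth
#'   consumed before `obs_day`).
#' @export
uvc_growth_curve <- function(initial, params, r_obs, obs_day, t_post,
                             thresholds = detection_thresholds(),
                             sample_interval = 1, dt = NULL) {
  stopifnot(inherits(initial, "cell_density_field"))
  if (t_post <= obs_day) {
    stop_config("`t_post` must be after `obs_day`.")
  }
  mm_removed <- attr(initial, "mm_removed") %||% 0
  pad <- ceiling(1.5 * mm_removed / params$velocity) + 5 * sample_interval
  duration <- (t_post - obs_day) + pad

  for (attempt in 1:4) {
    cfg <- sim_config(duration = duration, dt = dt,
                      sample_interval = sample_interval)
    curve <- simulate_uvc(initial, params, cfg, thresholds)
    t_star <- crossing_time(curve$time, curve$r_t1gd, r_obs)
    if (!is.na(t_star) && max(curve$time) - t_star >= t_post - obs_day) break
    duration <- duration * 2
    if (attempt == 4) {
      stop_estimation(sprintf(
        "Simulated tumour did not regrow to the observed radius (%.2f mm) and cover t_post within %.0f days; check the estimated kinetics.",
        r_obs, duration / 2))
    }
  }

  shifted <- curve$time - t_star + obs_day
  keep <- shifted >= obs_day - 1e-9 & shifted <= t_post + 1e-9
  interp_row <- function(t) {
    vapply(c("r_t1gd", "r_t2", "total_cells"), function(col) {
      stats::approx(shifted, curve[[col]], xout = t, ties = "ordered")$y
    }, numeric(1))
  }
  times <- sort(unique(c(obs_day, shifted[keep], t_post)))
  vals <- t(vapply(times, interp_row, numeric(3)))
  out <- tibble::tibble(time = times,
                        r_t1gd = vals[, 1], r_t2 = vals[, 2],
                        total_cells = vals[, 3])
  aligned <- new_growth_curve(out, params = params, thresholds = thresholds,
                              dt = attr(curve, "dt"),
                              clip_total = attr(curve, "clip_total"),
                              day0 = obs_day)
  attr(aligned, "alignment_shift") <- t_star
  aligned
}

# earliest time at which the piecewise-linear curve reaches value r
crossing_time <- function(times, radii, r) {
  if (radii[1] >= r) return(times[1])
  idx <- which(radii[-1] >= r & radii[-length(radii)] < r)
  if (length(idx) == 0) return(NA_real_)
  i <- idx[1]
  times[i] + (r - radii[i]) / (radii[i + 1] - radii[i]) *
    (times[i + 1] - times[i])
}

#' Score a patient from in-memory observations
#'
#' The per-patient method without any file handling: estimate the kinetic
#' parameters from the two pre-treatment observations, build the eroded
#' initial condition from the second, simulate the untreated virtual
#' control on the patient clock, and score the post-treatment T1Gd mask as
#' Days Gained. [run_patient()] wraps this with volume I/O and reports.
#'
#' @param pre1,pre2 Pre-treatment [tumor_observation()]s (chronological).
#' @param post_t1gd 3D binary post-treatment T1Gd mask.
#' @param post_day Day of the post-treatment scan.
#' @param domain [brain_domain()].
#' @param thresholds [detection_thresholds()].
#' @param erosion_fraction Fraction of the T1Gd SE radius eroded for the
#'   initial condition.
#' @param sample_interval,dt Simulation settings.
#' @param margin_source,margin_rule Estimation settings (see
#'   [estimate_parameters()]).
#' @return A [days_gained()] score with attributes `params`, `curve`,
#'   `initial`.
#' @export
score_observations <- function(pre1, pre2, post_t1gd, post_day, domain,
                               thresholds = detection_thresholds(),
                               erosion_fraction = 0.2,
                               sample_interval = 1, dt = NULL,
                               margin_source = "late",
                               margin_rule = "front_profile") {
  sp <- domain$spacing
  params <- estimate_parameters(pre1, pre2, thresholds, sp,
                                margin_source = margin_source,
                                margin_rule = margin_rule)
  initial <- build_initial_condition(pre2, domain, thresholds,
                                     erosion_fraction)
  r_obs <- se_radius(pre2$t1gd_mask, sp)
  curve <- uvc_growth_curve(initial, params, r_obs, pre2$day, post_day,
                            thresholds, sample_interval, dt)
  post_t1gd <- as_mask(post_t1gd, "post_t1gd") & domain$brain_mask
  score <- days_gained(curve, se_radius(post_t1gd, sp), post_day)
  attr(score, "params") <- params
  attr(score, "curve") <- curve
  attr(score, "initial") <- initial
  score
}

#' Per-patient scoring configuration
#'
#' Assembles and validates the inputs for [run_patient()]: file paths to the
#' six mask volumes, acquisition days, thresholds and simulation settings.
#' All paths are checked before any computation starts (fail fast).
#'
#' @param paths Named list with entries `brain_mask`, `pre1_t1gd`,
#'   `pre1_t2`, `pre2_t1gd`, `pre2_t2`, `post_t1gd` (NIfTI paths).
#' @param days Named list/vector with `pre1`, `pre2`, `post` (days).
#' @param patient_id Identifier used in reports and error messages.
#' @param thresholds [detection_thresholds()].
#' @param erosion_fraction Fraction of the T1Gd SE radius eroded for the
#'   initial condition (default 0.2).
#' @param sample_interval,dt Simulation settings (see [sim_config()]).
#' @param margin_source,margin_rule Estimation settings (see
#'   [estimate_parameters()]).
#' @param output_dir Directory for reports; `NULL` disables file output.
#' @return An object of class `patient_config`.
#' @export
patient_config <- function(paths, days, patient_id = "patient",
                           thresholds = detection_thresholds(),
                           erosion_fraction = 0.2,
                           sample_interval = 1, dt = NULL,
                           margin_source = "late",
                           margin_rule = "front_profile",
                           output_dir = NULL) {
  need <- c("brain_mask", "pre1_t1gd", "pre1_t2", "pre2_t1gd", "pre2_t2",
            "post_t1gd")
  missing_paths <- setdiff(need, names(paths))
  if (length(missing_paths)) {
    stop_config(paste0("Missing path(s) in config: ",
                       paste(missing_paths, collapse = ", "), "."))
  }
  absent <- unlist(paths[need])[!file.exists(unlist(paths[need]))]
  if (length(absent)) {
    stop_config(paste0("Input file(s) not found: ",
                       paste(absent, collapse = ", "), "."))
  }
  days <- as.list(days)
  if (!all(c("pre1", "pre2", "post") %in% names(days))) {
    stop_config("`days` needs entries pre1, pre2, post.")
  }
  structure(list(paths = paths, days = days, patient_id = patient_id,
                 thresholds = thresholds,
                 erosion_fraction = erosion_fraction,
                 sample_interval = sample_interval, dt = dt,
                 margin_source = margin_source, margin_rule = margin_rule,
                 output_dir = output_dir),
            class = "patient_config")
}

#' Load a per-patient YAML configuration
#'
#' Reads a human-editable YAML file with keys `paths`, `days` and optional
#' `patient_id`, `thresholds` (`t1gd_fraction`, `t2_fraction`,
#' `carrying_capacity`), `erosion_fraction`, `simulation`
#' (`sample_interval`, `dt`), `estimation` (`margin_source`, `margin_rule`)
#' and `output_dir`. Relative paths are resolved against the YAML file's
#' directory.
#'
#' @param path YAML file path.
#' @return A [patient_config()].
#' @export
read_patient_config <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("Config file not found: '%s'.", path))
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  paths <- lapply(y$paths, function(p) {
    if (!is.null(p) && !grepl("^(/|[A-Za-z]:)", p)) file.path(base, p) else p
  })
  thr <- do.call(detection_thresholds, y$thresholds %||% list())
  patient_config(
    paths = paths, days = y$days,
    patient_id = y$patient_id %||% "patient",
    thresholds = thr,
    erosion_fraction = y$erosion_fraction %||% 0.2,
    sample_interval = (y$simulation %||% list())$sample_interval %||% 1,
    dt = (y$simulation %||% list())$dt,
    margin_source = (y$estimation %||% list())$margin_source %||% "late",
    margin_rule = (y$estimation %||% list())$margin_rule %||% "front_profile",
    output_dir = y$output_dir)
}

#' Score one patient end to end
#'
#' Runs the full per-patient pipeline: read volumes, validate observations,
#' estimate the kinetic parameters from the two pre-treatment scans, build
#' the eroded initial condition from the second scan, simulate the untreated
#' virtual control to the post-treatment day, and score the observed
#' post-treatment T1Gd SE radius as Days Gained. If `output_dir` is set, the
#' growth-curve table (CSV), a JSON report (kinetics, erosion, score,
#' numerical-health quantities), the initial density volume with its
#' provenance sidecar, and a timestamped log are written there.
#'
#' @param config A [patient_config()] or path to a YAML config file.
#' @return The [days_gained()] score, with attributes `params`, `curve`,
#'   `report` (the report list).
#' @export
run_patient <- function(config) {
  if (is.character(config)) config <- read_patient_config(config)
  stopifnot(inherits(config, "patient_config"))
  out_dir <- config$output_dir
  logf <- start_log(out_dir, config$patient_id)

  stage <- function(name, expr) {
    tryCatch(expr, dg_error = function(e) {
      rlang::abort(sprintf("[%s / %s] %s", config$patient_id, name,
                           conditionMessage(e)),
                   class = class(e)[1], parent = e)
    })
  }

  logf("read", "loading volumes")
  vols <- stage("read", lapply(config$paths, read_volume))
  sp <- vols$brain_mask$spacing
  domain <- stage("read", brain_domain(vols$brain_mask$values != 0, sp,
                                       affine = vols$brain_mask$affine))
  obs <- stage("validate", list(
    pre1 = tumor_observation(vols$pre1_t1gd$values != 0,
                             vols$pre1_t2$values != 0,
                             config$days$pre1, domain = domain),
    pre2 = tumor_observation(vols$pre2_t1gd$values != 0,
                             vols$pre2_t2$values != 0,
                             config$days$pre2, domain = domain)))
  post_mask <- (vols$post_t1gd$values != 0) & domain$brain_mask

  logf("kinetics", "estimating D and rho")
  params <- stage("kinetics", estimate_parameters(
    obs$pre1, obs$pre2, config$thresholds, sp,
    margin_source = config$margin_source, margin_rule = config$margin_rule))
  logf("kinetics", sprintf("D = %.4g mm^2/day, rho = %.4g /day, v = %.4g mm/day",
                           params$D, params$rho, params$velocity))

  logf("initial_condition", "building eroded initial density field")
  initial <- stage("initial_condition", build_initial_condition(
    obs$pre2, domain, config$thresholds, config$erosion_fraction))
  logf("initial_condition", sprintf("mm_removed = %.2f", attr(initial, "mm_removed")))

  r_obs <- se_radius(obs$pre2$t1gd_mask, sp)
  logf("simulate", "running untreated virtual control")
  curve <- stage("simulate", uvc_growth_curve(
    initial, params, r_obs, obs$pre2$day, config$days$post,
    config$thresholds, config$sample_interval, config$dt))
  logf("simulate", sprintf("dt = %.3g days, clipped mass = %.3g",
                           attr(curve, "dt"), attr(curve, "clip_total")))

  r_post <- se_radius(post_mask, sp)
  score <- stage("days_gained", days_gained(curve, r_post, config$days$post))
  logf("days_gained", sprintf("score = %.1f days (%s)", score$score, score$method))

  report <- list(
    patient_id = config$patient_id,
    kinetics = list(D = params$D, rho = params$rho,
                    velocity = params$velocity,
                    infiltration_length = params$infiltration_length),
    thresholds = unclass(config$thresholds),
    erosion = list(fraction = config$erosion_fraction,
                   mm_removed = attr(initial, "mm_removed"),
                   eroded_r_t1gd = attr(initial, "eroded_r_t1gd"),
                   eroded_r_t2 = attr(initial, "eroded_r_t2")),
    observed = list(r_t1gd_pre1 = se_radius(obs$pre1$t1gd_mask, sp),
                    r_t1gd_pre2 = r_obs,
                    r_t2_pre2 = se_radius(obs$pre2$t2_mask, sp),
                    r_t1gd_post = r_post),
    curve = list(t_first = min(curve$time), t_last = max(curve$time),
                 r_first = curve$r_t1gd[1],
                 r_last = curve$r_t1gd[nrow(curve)],
                 alignment_shift = attr(curve, "alignment_shift")),
    numerical = list(dt = attr(curve, "dt"),
                     clip_total = attr(curve, "clip_total")),
    days_gained = list(score = score$score, matched_time = score$matched_time,
                       method = score$method, modality = score$modality,
                       t_post = score$t_post, r_post = score$r_post))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(curve)[, c("time", "r_t1gd", "r_t2",
                                              "total_cells")],
                     file.path(out_dir, "growth_curve.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    write_volume(file.path(out_dir, "initial_density.nii.gz"),
                 initial$values, sp, domain$affine)
    jsonlite::write_json(
      list(mm_removed = attr(initial, "mm_removed"),
           eroded_r_t1gd = attr(initial, "eroded_r_t1gd"),
           eroded_r_t2 = attr(initial, "eroded_r_t2"),
           thresholds = unclass(config$thresholds),
           erosion_fraction = config$erosion_fraction),
      file.path(out_dir, "initial_condition.json"),
      auto_unbox = TRUE, digits = 10, pretty = TRUE)
    logf("done", sprintf("reports written to %s", out_dir))
  }

  attr(score, "params") <- params
  attr(score, "curve") <- curve
  attr(score, "report") <- report
  score
}

start_log <- function(out_dir, id) {
  if (is.null(out_dir)) return(function(stage, msg) invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(out_dir, "run.log")
  function(stage, msg) {
    cat(sprintf("%s [%s] (%s) %s\n",
                format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), id, stage, msg),
        file = path, append = TRUE)
    invisible(NULL)
  }
}

#' Cohort-level threshold scan
#'
#' Loads a cohort table (CSV/TSV with columns `patient_id`, `days_gained`,
#' `time_to_event`, `event_observed`, `endpoint`), validates it, and runs
#' the constrained Kaplan-Meier threshold scan for one endpoint. If
#' `output_dir` is set, the scan table (CSV), the optimum summary (JSON)
#' and a p-value map figure (PNG) are written.
#'
#' @param cohort A data frame or path to a delimited file.
#' @param endpoint Endpoint to analyse (`"PFS"` or `"OS"`).
#' @param min_fraction Minimum fraction of patients on each side of an
#'   admissible split (default 0.20).
#' @param grid Candidate thresholds (default integer days over the observed
#'   score range).
#' @param output_dir Directory for outputs; `NULL` disables file output.
#' @return A [threshold_scan()].
#' @export
run_cohort <- function(cohort, endpoint = "PFS", min_fraction = 0.20,
                       grid = NULL, output_dir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort_table(cohort)
  cohort <- validate_survival_records(cohort)
  sub <- cohort[cohort$endpoint == endpoint, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop_validation(sprintf("No rows for endpoint '%s'.", endpoint))
  }
  scan <- threshold_scan(sub, min_fraction = min_fraction, grid = grid)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(scan),
                     file.path(output_dir, "threshold_scan.csv"),
                     row.names = FALSE)
    jsonlite::write_json(as.list(glance(scan)),
                         file.path(output_dir, "optimum.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    tryCatch({
      p <- autoplot(scan)
      ggplot2::ggsave(file.path(output_dir, "p_value_map.png"), p,
                      width = 7, height = 4, dpi = 150)
    }, error = function(e) dg_warn(paste("Could not write figure:",
                                         conditionMessage(e))))
  }
  scan
}

#' Read a cohort table from a delimited file
#'
#' @param path CSV (or tab-delimited `.tsv`) file with the cohort columns.
#' @return A validated tibble of survival records.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("Cohort table not found: '%s'.", path))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- tryCatch(utils::read.csv(path, sep = sep, stringsAsFactors = FALSE),
                 error = function(e) stop_format(sprintf(
                   "Could not parse '%s': %s", path, conditionMessage(e))))
  if ("event_observed" %in% names(df)) {
    df$event_observed <- as.logical(df$event_observed)
  }
  validate_survival_records(df)
}
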