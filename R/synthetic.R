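#' Synthetic brain domains
#'
#' Deterministic brain masks for testing and fixtures: a centred sphere, an
#' ellipsoid, or a connected two-lobe geometry whose midline constriction
#' exercises mask confinement of the simulated tumour.
#'
#' @param shape Integer length-3 grid size in voxels (each >= 16; >= 32 is
#'   needed for travelling-wave-regime tumours).
#' @param spacing Voxel size in mm.
#' @param geometry `"sphere"`, `"ellipsoid"` or `"two_lobe"`.
#' @return A [brain_domain()].
#' @examples
#' dom <- make_brain_domain(c(32, 32, 32))
#' sum(dom$brain_mask)
#' @export
make_brain_domain <- function(shape = c(64, 64, 64), spacing = c(1, 1, 1),
                              geometry = c("sphere", "ellipsoid", "two_lobe")) {
  geometry <- match.arg(geometry)
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 16) || min(shape * spacing) < 16) {
    stop_config("Grid must be at least 16 voxels and 16 mm along every axis.")
  }
  ext <- shape * spacing
  ctr <- (shape - 1) / 2 * spacing
  g <- voxel_centers(shape, spacing)
  mask <- switch(geometry,
    sphere = {
      r <- min(ext) / 2 - 2
      (g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2 <= r^2
    },
    ellipsoid = {
      ax <- ext / 2 * c(0.95, 0.8, 0.68) - 1
      ((g$x - ctr[1]) / ax[1])^2 + ((g$y - ctr[2]) / ax[2])^2 +
        ((g$z - ctr[3]) / ax[3])^2 <= 1
    },
    two_lobe = {
      off <- 0.22 * ext[1]
      r <- 0.30 * min(ext)
      lobe1 <- (g$x - (ctr[1] - off))^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2 <= r^2
      lobe2 <- (g$x - (ctr[1] + off))^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2 <= r^2
      # narrow bridge across the midline keeps the mask connected
      bridge <- abs(g$x - ctr[1]) <= off &
        (g$y - ctr[2])^2 + (g$z - ctr[3])^2 <= (0.35 * r)^2
      lobe1 | lobe2 | bridge
    })
  dim(mask) <- shape
  brain_domain(mask, spacing)
}

voxel_centers <- function(shape, spacing) {
  # voxel-centre coordinates in mm, 0-based indices
  list(
    x = array(rep((seq_len(shape[1]) - 1) * spacing[1],
                  times = shape[2] * shape[3]), dim = shape),
    y = array(rep(rep((seq_len(shape[2]) - 1) * spacing[2], each = shape[1]),
                  times = shape[3]), dim = shape),
    z = array(rep((seq_len(shape[3]) - 1) * spacing[3],
                  each = shape[1] * shape[2]), dim = shape))
}

# Spherical seed with the established travelling-front radial profile:
# density follows the critical Fisher front u(z) with z measured outward
# from the requested T1Gd (f1-contour) radius in units of the infiltration
# length. A glioblastoma at presentation has been growing for a long time,
# so starting the ground truth from the mature wave profile (rather than a
# point source) is both realistic and avoids the slow pulled-front
# establishment transient.
seed_field <- function(domain, params, thresholds, seed_radius = 10,
                       center = NULL) {
  sp <- domain$spacing
  ctr <- center %||% ((domain$shape - 1) / 2 * sp)
  g <- voxel_centers(domain$shape, sp)
  d <- sqrt((g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2)
  l <- params$infiltration_length
  prof <- front_profile()
  z_f1 <- front_contour_z(thresholds$t1gd_fraction)
  vals <- prof((d - seed_radius) / l + z_f1)
  vals[vals < 1e-6] <- 0
  dim(vals) <- domain$shape
  cell_density_field(vals, domain, day = 0)
}

#' Generate a virtual patient with known ground truth
#'
#' Runs the growth model from a small central seed with known `D` and `rho`,
#' thresholds the density at the two pre-treatment days to fabricate
#' co-registered T1Gd/T2 observations, and plants a known therapy effect:
#' the post-treatment observation shows the ground-truth tumour as it was
#' `response_days` earlier, so the pipeline's expected Days Gained score is
#' `response_days` by construction.
#'
#' Defaults emulate a median-kinetics glioblastoma (radial velocity about
#' 23 mm/year, infiltration length 1.6 mm) observed twice before therapy
#' (days 40 and 70) and once after (day 150), inside a 64 mm spherical
#' brain: the full T2 abnormality then stays clear of the domain boundary
#' for the whole course.
#'
#' @param D,rho Ground-truth kinetics (mm^2/day, 1/day).
#' @param days Numeric length-3 `(t_pre1, t_pre2, t_post)` in days from the
#'   seed, strictly increasing, with `t_pre2 - t_pre1 >= 5`.
#' @param response_days Planted therapy effect in days (>= 0; must not push
#'   the post observation before day 0).
#' @param domain A [brain_domain()]; default 64^3 sphere at 1 mm.
#' @param thresholds [detection_thresholds()].
#' @param seed_radius Radius (mm) of the saturated seed core.
#' @param noise_prob Per-voxel probability of flipping a mask boundary voxel
#'   (segmentation noise); 0 disables.
#' @param seed RNG seed for the segmentation noise (the solver itself is
#'   deterministic).
#' @return An object of class `virtual_patient`: `true_params`, `domain`,
#'   `thresholds`, `pre1`, `pre2`, `post` ([tumor_observation()]s; `post`
#'   is stamped with day `t_post`), `true_days_gained`, `true_curve` (the
#'   ground-truth growth curve), `seed`.
#' @export
make_virtual_patient <- function(D = 0.05, rho = 0.02,
                                 days = c(40, 70, 150), response_days = 0,
                                 domain = make_brain_domain(),
                                 thresholds = detection_thresholds(),
                                 seed_radius = 8, noise_prob = 0, seed = 1L) {
  params <- kinetic_parameters(D, rho)
  if (length(days) != 3 || is.unsorted(days, strictly = TRUE)) {
    stop_config("`days` must be strictly increasing (t_pre1, t_pre2, t_post).")
  }
  if (days[2] - days[1] < 5) {
    stop_interval("Pre-treatment observations must be at least 5 days apart.")
  }
  if (response_days < 0 || days[3] - response_days < 0) {
    stop_config("`response_days` must be >= 0 and not push the post observation before day 0.")
  }
  t_obs_post <- days[3] - response_days
  rec <- sort(unique(c(days[1], days[2], t_obs_post)))

  initial <- seed_field(domain, params, thresholds, seed_radius)
  cfg <- sim_config(duration = days[3], sample_interval = 1, record_times = rec)
  curve <- simulate_uvc(initial, params, cfg, thresholds)
  snaps <- curve_fields(curve)
  snap_at <- function(t) snaps[[sprintf("t%g", t)]]

  obs_from_field <- function(field, day, rng_offset) {
    t1 <- field$values >= thresholds$t1gd_fraction
    t2 <- field$values >= thresholds$t2_fraction
    if (noise_prob > 0) {
      t1 <- jiggle_mask(t1, noise_prob, seed + rng_offset)
      t2 <- jiggle_mask(t2, noise_prob, seed + rng_offset + 1L)
    }
    suppressWarnings(tumor_observation(t1, t2, day, domain = domain))
  }

  pre1 <- obs_from_field(snap_at(days[1]), days[1], 0L)
  pre2 <- obs_from_field(snap_at(days[2]), days[2], 10L)
  post <- obs_from_field(snap_at(t_obs_post), days[3], 20L)

  structure(list(true_params = params, domain = domain,
                 thresholds = thresholds,
                 pre1 = pre1, pre2 = pre2, post = post,
                 true_days_gained = response_days,
                 true_curve = curve, seed = seed),
            class = "virtual_patient")
}

# Flip boundary voxels of a binary mask with given probability (both
# directions: erode foreground boundary voxels, dilate background boundary
# voxels), reproducibly.
jiggle_mask <- function(mask, prob, seed) {
  inner <- erode_layer(mask)
  boundary_fg <- mask & !inner
  dil <- !erode_layer(!mask)
  boundary_bg <- dil & !mask
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed({
    flip_fg <- boundary_fg & array(runif(length(mask)) < prob, dim = dim(mask))
    flip_bg <- boundary_bg & array(runif(length(mask)) < prob, dim = dim(mask))
  })
  out <- mask
  out[flip_fg] <- FALSE
  out[flip_bg] <- TRUE
  out
}

#' Generate a synthetic survival cohort with a planted Days Gained effect
#'
#' Draws Days Gained scores from a clipped normal distribution matching the
#' reported cohort spread (mean 134, sd 111, range -77 to 512) and
#' exponential event times whose hazard is divided by `hazard_ratio` for
#' scores at or above `threshold`, with independent exponential censoring.
#'
#' @param n Number of patients (>= 10).
#' @param threshold Score (days) at which the hazard drops.
#' @param hazard_ratio Ratio of below-threshold to at-or-above-threshold
#'   hazard (> 0; 1 plants no effect).
#' @param censoring_rate Approximate fraction censored, in `[0, 1)`.
#' @param seed RNG seed.
#' @param endpoint Endpoint tag for the records (`"PFS"` or `"OS"`).
#' @param median_survival Baseline (below-threshold) median event time in
#'   days.
#' @param score_mean,score_sd,score_range Parameters of the clipped normal
#'   score distribution.
#' @return A tibble of survival records (see [validate_survival_records()]).
#' @export
make_survival_cohort <- function(n, threshold = 100, hazard_ratio = 3,
                                 censoring_rate = 0.2, seed = 1L,
                                 endpoint = "PFS", median_survival = 400,
                                 score_mean = 134, score_sd = 111,
                                 score_range = c(-77, 512)) {
  if (n < 10) stop_config("`n` must be at least 10.")
  if (hazard_ratio <= 0) stop_config("`hazard_ratio` must be positive.")
  if (censoring_rate < 0 || censoring_rate >= 1) {
    stop_config("`censoring_rate` must lie in [0, 1).")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  scores <- pmin(pmax(rnorm(n, score_mean, score_sd), score_range[1]),
                 score_range[2])
  lambda0 <- log(2) / median_survival
  lambda <- ifelse(scores >= threshold, lambda0 / hazard_ratio, lambda0)
  t_event <- rexp(n, rate = lambda)
  if (censoring_rate > 0) {
    # for independent exponentials, P(censor first) = lc / (lc + le)
    lc <- mean(lambda) * censoring_rate / (1 - censoring_rate)
    t_cens <- rexp(n, rate = lc)
  } else {
    t_cens <- rep(Inf, n)
  }
  tibble::tibble(
    patient_id = sprintf("VP%03d", seq_len(n)),
    days_gained = scores,
    time_to_event = pmin(t_event, t_cens),
    event_observed = t_event <= t_cens,
    endpoint = endpoint)
}

#' Write a self-contained fixture directory
#'
#' Materialises a virtual patient (volumes as NIfTI), a synthetic survival
#' cohort (CSV) and a manifest (JSON, recording the ground truth and every
#' generator argument) into a directory, so the command-line pipeline can be
#' exercised without any external data.
#'
#' @param dir Output directory (created if needed).
#' @param patient A `virtual_patient` (default: one with the package
#'   defaults).
#' @param cohort A cohort tibble (default: `make_survival_cohort(100)`).
#' @return `dir`, invisibly; files `brain_mask.nii.gz`,
#'   `{pre1,pre2,post}_{t1gd,t2}.nii.gz`, `cohort.csv`, `manifest.json`.
#' @export
write_fixture_dir <- function(dir, patient = NULL, cohort = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  patient <- patient %||% make_virtual_patient()
  cohort <- cohort %||% make_survival_cohort(100)
  sp <- patient$domain$spacing
  wv <- function(name, arr) write_volume(file.path(dir, name), arr, sp)
  wv("brain_mask.nii.gz", patient$domain$brain_mask)
  for (ob in c("pre1", "pre2", "post")) {
    wv(paste0(ob, "_t1gd.nii.gz"), patient[[ob]]$t1gd_mask)
    wv(paste0(ob, "_t2.nii.gz"), patient[[ob]]$t2_mask)
  }
  utils::write.csv(cohort, file.path(dir, "cohort.csv"), row.names = FALSE)
  manifest <- list(
    true_D = patient$true_params$D,
    true_rho = patient$true_params$rho,
    true_velocity = patient$true_params$velocity,
    true_days_gained = patient$true_days_gained,
    days = list(pre1 = patient$pre1$day, pre2 = patient$pre2$day,
                post = patient$post$day),
    spacing = sp,
    shape = patient$domain$shape,
    thresholds = unclass(patient$thresholds),
    seed = patient$seed,
    cohort_n = nrow(cohort))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
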