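#' Simulation configuration
#'
#' Controls the explicit finite-difference integration of the growth model.
#' The forward-Euler scheme is stable for
#' `dt <= 1 / (2 D sum(1/h_i^2))` (which reduces to `h^2/(6D)` on an
#' isotropic grid with spacing `h`); when `dt` is `NULL` it is chosen
#' automatically as 0.9 times that bound, additionally capped at
#' `0.2 / rho` so the logistic reaction is resolved, and at the sampling
#' interval.
#'
#' @param dt Time step in days, or `NULL` for automatic.
#' @param sample_interval Days between growth-curve samples (default 1).
#' @param duration Simulated time span in days.
#' @param store_fields Store the density field at every sample (memory
#'   heavy; default `FALSE`).
#' @param record_times Optional vector of times (days from start) at which
#'   to store density snapshots regardless of `store_fields`.
#' @param seed Unused by the deterministic solver; reserved.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(duration, dt = NULL, sample_interval = 1,
                       store_fields = FALSE, record_times = NULL, seed = NULL) {
  if (length(duration) != 1 || !is.finite(duration) || duration < 0) {
    stop_config("`duration` must be a single non-negative number of days.")
  }
  if (!is.null(dt) && (length(dt) != 1 || !is.finite(dt) || dt <= 0)) {
    stop_config("`dt` must be a positive time step in days (or NULL for auto).")
  }
  if (sample_interval <= 0) stop_config("`sample_interval` must be positive.")
  if (!is.null(record_times) &&
      (any(!is.finite(record_times)) || any(record_times < 0) ||
       any(record_times > duration))) {
    stop_config("`record_times` must lie within [0, duration].")
  }
  structure(list(duration = duration, dt = dt,
                 sample_interval = sample_interval,
                 store_fields = isTRUE(store_fields),
                 record_times = record_times, seed = seed),
            class = "sim_config")
}

stable_dt <- function(D, rho, spacing) {
  bound <- if (D > 0) 1 / (2 * D * sum(1 / spacing^2)) else Inf
  dt <- 0.9 * bound
  if (rho > 0) dt <- min(dt, 0.2 / rho)
  dt
}

#' Advance a density field by one (or more) explicit time steps
#'
#' One forward-Euler update of the normalised proliferation-invasion
#' equation `dc/dt = div(D grad c) + rho c (1 - c)` with a 7-point Laplacian
#' and zero-flux conditions at the brain-mask boundary. Values are clipped
#' to `[0, 1]` only to absorb round-off; the total clipped magnitude is
#' accumulated on the returned field as attribute `clip_total`.
#'
#' @param field [cell_density_field()].
#' @param params [kinetic_parameters()].
#' @param dt Time step in days; must respect the stability bound (see
#'   [sim_config()]).
#' @param nsteps Number of consecutive steps (default 1).
#' @return The advanced [cell_density_field()], `dt * nsteps` days later.
#' @export
fkpp_step <- function(field, params, dt, nsteps = 1L) {
  stopifnot(inherits(field, "cell_density_field"),
            inherits(params, "kinetic_parameters"))
  sp <- field$domain$spacing
  bound <- if (params$D > 0) 1 / (2 * params$D * sum(1 / sp^2)) else Inf
  if (dt > bound + 1e-12) {
    stop_stability(sprintf(
      "dt = %.4g days violates the explicit stability bound %.4g days for D = %.4g mm^2/day on this grid.",
      dt, bound, params$D))
  }
  res <- fkpp_run_cpp(field$values, field$domain$brain_mask,
                      as.integer(field$domain$shape), sp,
                      params$D, params$rho, dt, as.integer(nsteps))
  out <- field
  out$values <- res$field
  out$day <- field$day + dt * nsteps
  attr(out, "clip_total") <- (attr(field, "clip_total") %||% 0) + res$clip_total
  out
}

measure_field <- function(values, spacing, thresholds) {
  voxvol <- prod(spacing)
  n1 <- sum(values >= thresholds$t1gd_fraction)
  n2 <- sum(values >= thresholds$t2_fraction)
  c(r_t1gd = (3 * n1 * voxvol / (4 * pi))^(1 / 3),
    r_t2 = (3 * n2 * voxvol / (4 * pi))^(1 / 3),
    total_cells = sum(values) * voxvol / 1000 * thresholds$carrying_capacity)
}

#' Simulate the untreated virtual control
#'
#' Integrates the growth model from an initial cell-density field for
#' `config$duration` days, recording the growth curve: the T1Gd and T2
#' spherically-equivalent radii of the imageable regions (densities at or
#' above each detection fraction) and the total tumour cell count, sampled
#' every `config$sample_interval` days including both endpoints. The solver
#' is deterministic: identical inputs give identical curves.
#'
#' @param initial [cell_density_field()] to start from.
#' @param params [kinetic_parameters()].
#' @param config [sim_config()].
#' @param thresholds [detection_thresholds()].
#' @return A `growth_curve`: a tibble with columns `time` (days from
#'   simulation start), `r_t1gd`, `r_t2` (mm), `total_cells`, carrying
#'   attributes `params`, `thresholds`, `dt`, `clip_total`, `day0` (the
#'   initial field's day) and, if requested, `fields` (named list of
#'   snapshots) .
#' @export
simulate_uvc <- function(initial, params, config,
                         thresholds = detection_thresholds()) {
  stopifnot(inherits(initial, "cell_density_field"),
            inherits(params, "kinetic_parameters"),
            inherits(config, "sim_config"))
  sp <- initial$domain$spacing
  dt_base <- config$dt %||% min(stable_dt(params$D, params$rho, sp),
                                config$sample_interval)
  bound <- if (params$D > 0) 1 / (2 * params$D * sum(1 / sp^2)) else Inf
  if (dt_base > bound + 1e-12) {
    stop_stability(sprintf(
      "dt = %.4g days violates the explicit stability bound %.4g days.",
      dt_base, bound))
  }

  times <- unique(c(seq(0, config$duration, by = config$sample_interval),
                    config$duration))
  record_times <- sort(unique(config$record_times))
  if (config$store_fields) record_times <- times
  sample_times <- sort(unique(c(times, record_times)))

  field <- initial
  rows <- vector("list", length(sample_times))
  fields <- list()
  clip_total <- 0
  t_now <- 0
  for (i in seq_along(sample_times)) {
    t_target <- sample_times[i]
    gap <- t_target - t_now
    if (gap > 1e-12) {
      nsub <- ceiling(gap / dt_base - 1e-9)
      res <- fkpp_run_cpp(field$values, field$domain$brain_mask,
                          as.integer(field$domain$shape), sp,
                          params$D, params$rho, gap / nsub, as.integer(nsub))
      field$values <- res$field
      clip_total <- clip_total + res$clip_total
      t_now <- t_target
    }
    m <- measure_field(field$values, sp, thresholds)
    rows[[i]] <- c(time = t_target, m)
    if (t_target %in% record_times) {
      fields[[sprintf("t%g", t_target)]] <-
        cell_density_field(field$values, initial$domain,
                           day = initial$day + t_target)
    }
  }
  curve <- tibble::as_tibble(do.call(rbind, rows))
  curve <- curve[curve$time %in% times, , drop = FALSE]
  new_growth_curve(curve, params = params, thresholds = thresholds,
                   dt = dt_base, clip_total = clip_total,
                   day0 = initial$day,
                   fields = if (length(fields)) fields else NULL)
}

new_growth_curve <- function(df, params, thresholds, dt = NA_real_,
                             clip_total = 0, day0 = 0, fields = NULL) {
  structure(df,
            class = c("growth_curve", class(tibble::tibble())),
            params = params, thresholds = thresholds, dt = dt,
            clip_total = clip_total, day0 = day0, fields = fields)
}

#' Extract stored density snapshots from a growth curve
#'
#' @param curve A `growth_curve` from [simulate_uvc()] run with
#'   `store_fields = TRUE` or `record_times` set.
#' @return Named list of [cell_density_field()]s (possibly empty).
#' @export
curve_fields <- function(curve) {
  attr(curve, "fields") %||% list()
}

#' @rdname simulate_uvc
#' @param x A `growth_curve`.
#' @param ... Unused.
#' @export
glance.growth_curve <- function(x, ...) {
  p <- attr(x, "params")
  tibble::tibble(
    n_samples = nrow(x),
    duration = max(x$time) - min(x$time),
    dt = attr(x, "dt"),
    clip_total = attr(x, "clip_total"),
    D = p$D, rho = p$rho, velocity = p$velocity,
    r_t1gd_first = x$r_t1gd[1], r_t1gd_last = x$r_t1gd[nrow(x)])
}
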