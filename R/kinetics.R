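#' Imaging detection thresholds
#'
#' Fractions of the tissue carrying capacity at which tumour cell density
#' becomes visible on each MRI modality: the T1Gd-enhancing core corresponds
#' to densities at or above 80% of carrying capacity, the T2/FLAIR
#' abnormality to densities at or above 16%. The carrying capacity is the
#' maximum tissue cell density, 1e8 cells/cm^3.
#'
#' @param t1gd_fraction T1Gd visibility threshold as a fraction of carrying
#'   capacity (default 0.80).
#' @param t2_fraction T2 visibility threshold (default 0.16); must satisfy
#'   `0 < t2_fraction < t1gd_fraction < 1`.
#' @param carrying_capacity Cells per cm^3 (default 1e8); only used to
#'   convert integrated density into cell counts.
#' @return An object of class `detection_thresholds`.
#' @export
detection_thresholds <- function(t1gd_fraction = 0.80, t2_fraction = 0.16,
                                 carrying_capacity = 1e8) {
  if (!(t2_fraction > 0 && t2_fraction < t1gd_fraction && t1gd_fraction < 1)) {
    stop_config("Thresholds must satisfy 0 < t2_fraction < t1gd_fraction < 1.")
  }
  if (carrying_capacity <= 0) stop_config("`carrying_capacity` must be positive.")
  structure(list(t1gd_fraction = t1gd_fraction, t2_fraction = t2_fraction,
                 carrying_capacity = carrying_capacity),
            class = "detection_thresholds")
}

#' Patient-specific kinetic parameters
#'
#' The two rates of the proliferation-invasion model: net diffusivity `D`
#' (mm^2/day) and net proliferation rate `rho` (1/day), with the derived
#' asymptotic front velocity `2 sqrt(D rho)` (mm/day) and infiltration
#' length `sqrt(D / rho)` (mm).
#'
#' @param D Net diffusivity, mm^2/day (>= 0; zero gives pure logistic
#'   growth, useful for validation).
#' @param rho Net proliferation rate, 1/day (>= 0; zero gives pure
#'   diffusion). At least one rate must be positive.
#' @return An object of class `kinetic_parameters`.
#' @export
kinetic_parameters <- function(D, rho) {
  if (length(D) != 1 || !is.finite(D) || D < 0) {
    stop_config("`D` must be a single non-negative diffusivity in mm^2/day.")
  }
  if (length(rho) != 1 || !is.finite(rho) || rho < 0) {
    stop_config("`rho` must be a single non-negative rate in 1/day.")
  }
  if (D == 0 && rho == 0) {
    stop_config("At least one of `D` and `rho` must be positive.")
  }
  structure(list(D = D, rho = rho,
                 velocity = 2 * sqrt(D * rho),
                 infiltration_length = sqrt(D / rho)),
            class = "kinetic_parameters")
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat(sprintf(
    "<kinetic_parameters> D = %.4g mm^2/day, rho = %.4g /day, v = %.4g mm/day, l = %.4g mm\n",
    x$D, x$rho, x$velocity, x$infiltration_length))
  invisible(x)
}

#' @rdname kinetic_parameters
#' @param x A `kinetic_parameters` object.
#' @param ... Unused.
#' @export
tidy.kinetic_parameters <- function(x, ...) {
  tibble::tibble(
    term = c("D", "rho", "velocity", "infiltration_length"),
    estimate = c(x$D, x$rho, x$velocity, x$infiltration_length),
    unit = c("mm^2/day", "1/day", "mm/day", "mm"))
}

#' Radial growth velocity from two pre-treatment radii
#'
#' The linear radial expansion velocity of the T1Gd SE radius between the two
#' pre-treatment scans. A minimum of five days between observations is
#' required for the rate to be measurable on routine imaging.
#'
#' @param r_early,r_late T1Gd SE radii in mm at the two observations.
#' @param day_early,day_late Acquisition days.
#' @return Velocity in mm/day.
#' @export
estimate_velocity <- function(r_early, r_late, day_early, day_late) {
  dt <- day_late - day_early
  if (!is.finite(dt) || dt < 5) {
    stop_interval(sprintf(
      "Only %.1f days between pre-treatment observations; at least 5 are required.",
      dt))
  }
  v <- (r_late - r_early) / dt
  if (!is.finite(v) || v <= 0) {
    stop_estimation(sprintf(
      "Non-positive radial velocity (%.3g mm/day) from radii %.2f -> %.2f mm; growth kinetics cannot be estimated.",
      v, r_early, r_late),
      r_early = r_early, r_late = r_late)
  }
  v
}

#' Critical Fisher-KPP front profile
#'
#' The travelling-wave profile `u(z)` of the normalised Fisher-KPP equation
#' at the critical speed, in the co-moving coordinate `z` measured in units
#' of the infiltration length `sqrt(D/rho)`: the solution of
#' `u'' + 2 u' + u (1 - u) = 0` with `u(-inf) = 1`, `u(+inf) = 0`.
#' Integrated by shooting forward along the unstable manifold of the
#' saturated state (`u = 1 - delta e^{(sqrt(2)-1) z}` for small `delta`),
#' which is the numerically stable construction; for the critical and all
#' supercritical speeds this trajectory is the front. The profile is
#' translated so that `u(0) = 1/2`.
#'
#' @return A function `u(z)` (vectorised), decreasing from 1 to 0.
#' @export
front_profile <- function() {
  cached <- .dg_cache[["profile"]]
  if (!is.null(cached)) return(cached)
  h <- 0.002
  mu <- sqrt(2) - 1
  delta <- 1e-9
  u <- 1 - delta
  up <- -mu * delta
  f <- function(u, up) c(up, -2 * up - u * (1 - u))
  nstep <- ceiling(80 / h)
  zs <- us <- numeric(nstep)
  z <- 0
  for (i in seq_len(nstep)) {
    k1 <- f(u, up)
    k2 <- f(u + h / 2 * k1[1], up + h / 2 * k1[2])
    k3 <- f(u + h / 2 * k2[1], up + h / 2 * k2[2])
    k4 <- f(u + h * k3[1], up + h * k3[2])
    u <- u + h / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
    up <- up + h / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
    z <- z + h
    zs[i] <- z; us[i] <- u
    if (u < 1e-10) break
  }
  zs <- zs[seq_len(i)]; us <- us[seq_len(i)]
  j <- which(us < 0.5)[1] # us is decreasing in z
  z_half <- zs[j - 1] + (us[j - 1] - 0.5) / (us[j - 1] - us[j]) * (zs[j] - zs[j - 1])
  fn <- stats::approxfun(zs - z_half, us, yleft = 1, yright = 0)
  .dg_cache[["profile"]] <- fn
  fn
}

#' Dimensionless T1Gd-to-T2 margin of the travelling front
#'
#' The distance, in units of the infiltration length `sqrt(D/rho)`, between
#' the `f1` and `f2` density contours of the critical-speed Fisher-KPP
#' travelling front (see [front_profile()]). For the default thresholds
#' (0.80, 0.16) the constant is about 6.106. The pure exponential-tail
#' linearisation `log(f1/f2) = log(5) = 1.609` underestimates it badly,
#' because the critical front decays like `z e^{-z}` rather than a plain
#' exponential and the 0.80 contour sits in the saturated region, so the
#' full profile is used by default when converting an imaging margin into
#' an infiltration length.
#'
#' @param f1,f2 Upper and lower density fractions, `0 < f2 < f1 < 1`.
#' @return Margin in units of the infiltration length.
#' @export
front_margin_constant <- function(f1 = 0.80, f2 = 0.16) {
  if (!(f2 > 0 && f2 < f1 && f1 < 1)) {
    stop_config("Need 0 < f2 < f1 < 1.")
  }
  key <- sprintf("%.12g|%.12g", f1, f2)
  cached <- .dg_cache[[key]]
  if (!is.null(cached)) return(cached)
  prof <- front_profile()
  zg <- seq(-20, 60, by = 0.001)
  ug <- prof(zg)
  z_at <- function(val) { # ug is non-increasing in zg
    i <- which(ug < val)[1]
    zg[i - 1] + (ug[i - 1] - val) / (ug[i - 1] - ug[i]) * (zg[i] - zg[i - 1])
  }
  margin <- z_at(f2) - z_at(f1)
  .dg_cache[[key]] <- margin
  margin
}

.dg_cache <- new.env(parent = emptyenv())

# co-moving coordinate (units of infiltration length) at which the critical
# front passes through density `frac`
front_contour_z <- function(frac) {
  prof <- front_profile()
  zg <- seq(-20, 60, by = 0.001)
  ug <- prof(zg)
  i <- which(ug < frac)[1]
  zg[i - 1] + (ug[i - 1] - frac) / (ug[i - 1] - ug[i]) * (zg[i] - zg[i - 1])
}

#' Estimate D and rho from two pre-treatment observations
#'
#' Decomposes the observed growth into the two kinetic rates via the
#' travelling-wave relations of the Fisher-KPP model: the T1Gd radial
#' velocity gives `v = 2 sqrt(D rho)`, and the T2-minus-T1Gd SE-radius
#' margin gives the infiltration length `l = sqrt(D/rho) = margin / kappa`.
#' Then `D = (v/2) l` and `rho = (v/2) / l`.
#'
#' With `margin_rule = "front_profile"` (default) `kappa` is the
#' dimensionless contour separation of the actual critical-speed front (see
#' [front_margin_constant()]), which makes the estimator consistent with the
#' simulator's own wave profile. `margin_rule = "exponential_tail"` uses the
#' classical leading-edge linearisation `kappa = log(f1/f2)`.
#'
#' @param obs_early,obs_late [tumor_observation()]s at the two pre-treatment
#'   times (at least 5 days apart).
#' @param thresholds [detection_thresholds()].
#' @param spacing Voxel size in mm.
#' @param margin_source Which observation supplies the T2-T1Gd margin:
#'   the `"late"` scan (default; it also seeds the simulation) or the
#'   `"mean"` of both.
#' @param margin_rule `"front_profile"` (default) or `"exponential_tail"`.
#' @return A [kinetic_parameters()] object.
#' @export
estimate_parameters <- function(obs_early, obs_late,
                                thresholds = detection_thresholds(),
                                spacing = c(1, 1, 1),
                                margin_source = c("late", "mean"),
                                margin_rule = c("front_profile", "exponential_tail")) {
  margin_source <- match.arg(margin_source)
  margin_rule <- match.arg(margin_rule)
  stopifnot(inherits(obs_early, "tumor_observation"),
            inherits(obs_late, "tumor_observation"))
  r1 <- se_radius(obs_early$t1gd_mask, spacing)
  r2 <- se_radius(obs_late$t1gd_mask, spacing)
  v <- estimate_velocity(r1, r2, obs_early$day, obs_late$day)

  margin_late <- se_radius(obs_late$t2_mask, spacing) - r2
  margin <- if (margin_source == "late") {
    margin_late
  } else {
    mean(c(margin_late, se_radius(obs_early$t2_mask, spacing) - r1))
  }
  if (!is.finite(margin) || margin <= 0) {
    stop_margin(sprintf(
      "T2 SE radius does not exceed the T1Gd SE radius (margin %.3g mm); the infiltration gradient cannot be estimated.",
      margin))
  }
  kappa <- switch(margin_rule,
    front_profile = front_margin_constant(thresholds$t1gd_fraction,
                                          thresholds$t2_fraction),
    exponential_tail = log(thresholds$t1gd_fraction / thresholds$t2_fraction))
  l <- margin / kappa
  kinetic_parameters(D = (v / 2) * l, rho = (v / 2) / l)
}
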