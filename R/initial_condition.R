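#' Normalised tumour cell-density field
#'
#' A 3D field of tumour cell density divided by the tissue carrying
#' capacity, so values lie in `[0, 1]`, defined on a [brain_domain()] and
#' stamped with a time in days. Density is identically zero outside the
#' brain mask.
#'
#' @param values 3D numeric array in `[0, 1]`.
#' @param domain A [brain_domain()] on the same grid.
#' @param day Time stamp in days.
#' @return An object of class `cell_density_field`.
#' @export
cell_density_field <- function(values, domain, day = 0) {
  stopifnot(inherits(domain, "brain_domain"))
  if (is.null(dim(values)) || length(dim(values)) != 3) {
    stop_dimension("`values` must be a 3D array.")
  }
  check_same_grid(dim(values), domain$shape, "density field")
  if (anyNA(values) || min(values) < 0 || max(values) > 1) {
    stop_validation("Density values must lie in [0, 1] with no NAs.")
  }
  values[!domain$brain_mask] <- 0
  structure(list(values = values, domain = domain, day = as.numeric(day)),
            class = "cell_density_field")
}

#' @export
print.cell_density_field <- function(x, ...) {
  cat(sprintf("<cell_density_field> day %.1f, max %.3f, %d voxels > 0\n",
              x$day, max(x$values), sum(x$values > 0)))
  invisible(x)
}

#' Build the simulation's initial cell-density field
#'
#' Constructs the untreated-virtual-control starting field from the second
#' pre-treatment observation:
#'
#' 1. The T1Gd mask is eroded perimeter-by-perimeter until its SE radius has
#'    shrunk by `erosion_fraction` (default 20%); the T2 mask is eroded by
#'    the same number of millimetres.
#' 2. Voxels inside the eroded T1Gd region are set to density 0.80 (the T1Gd
#'    visibility threshold).
#' 3. Between the eroded T1Gd and T2 surfaces the density follows a Gaussian
#'    ramp in the normalised coordinate `u = d1 / (d1 + d2)` (distances to
#'    the two surfaces), scaled so the ramp hits the T2 visibility fraction
#'    exactly at the T2 surface.
#' 4. Beyond the eroded T2 surface the density continues as
#'    `f2 * exp(-d2^2 / (2 sigma^2))` with `sigma` tied to the eroded
#'    T2-T1Gd SE-radius margin, so the outer tail depends only on the
#'    distance to the T2 perimeter and the SE radii.
#' 5. Values are clipped to `[0, 1]`, zeroed outside the brain mask, and
#'    densities below 1e-6 are floored to 0.
#'
#' The erosion exists so that, once the simulated tumour has regrown to the
#' observed pre-treatment size, its imageable surfaces match the observed
#' masks in shape rather than starting already at the observed boundary.
#'
#' @param obs [tumor_observation()] (the second pre-treatment scan).
#' @param domain [brain_domain()].
#' @param thresholds [detection_thresholds()].
#' @param erosion_fraction Fraction of the T1Gd SE radius to erode (default
#'   0.2).
#' @return A [cell_density_field()] stamped with `obs$day`, with attributes
#'   `mm_removed`, `eroded_r_t1gd`, `eroded_r_t2` recording the construction.
#' @export
build_initial_condition <- function(obs, domain,
                                    thresholds = detection_thresholds(),
                                    erosion_fraction = 0.2) {
  stopifnot(inherits(obs, "tumor_observation"), inherits(domain, "brain_domain"))
  check_same_grid(dim(obs$t1gd_mask), domain$shape, "observation")
  if (!any(obs$t1gd_mask)) stop_degenerate("T1Gd mask is empty.")
  sp <- domain$spacing
  f1 <- thresholds$t1gd_fraction
  f2 <- thresholds$t2_fraction

  er1 <- erode_by_radius_fraction(obs$t1gd_mask, sp, erosion_fraction,
                                  partial = TRUE)
  er2 <- erode_by_millimeters(obs$t2_mask, sp, er1$mm_removed, partial = TRUE)
  t1 <- er1$mask
  t2 <- er2$mask | t1 # keep nesting under aggressive T2 erosion
  r1 <- se_radius(t1, sp)
  r2 <- se_radius(t2, sp)
  dr <- r2 - r1
  if (dr <= 0) {
    stop_margin(sprintf(
      "Eroded T2 SE radius (%.2f mm) does not exceed eroded T1Gd SE radius (%.2f mm).",
      r2, r1))
  }

  a <- sqrt(2 * log(f1 / f2)) # ramp shape: f1 * exp(-(a u)^2 / 2) = f2 at u = 1
  sigma <- dr / a

  d1 <- distance_transform(t1, sp)  # mm to eroded T1Gd region
  d2in <- distance_transform(!t2, sp) # mm to eroded T2 surface, from inside
  d2out <- distance_transform(t2, sp) # mm to eroded T2 region, from outside

  vals <- array(0, dim = domain$shape)
  vals[t1] <- f1
  ring <- t2 & !t1
  if (any(ring)) {
    u <- d1[ring] / (d1[ring] + d2in[ring])
    vals[ring] <- f1 * exp(-(a * u)^2 / 2)
  }
  outside <- !t2 & domain$brain_mask
  vals[outside] <- f2 * exp(-d2out[outside]^2 / (2 * sigma^2))

  vals[vals < 1e-6] <- 0
  vals <- pmin(pmax(vals, 0), 1)
  dim(vals) <- domain$shape

  field <- cell_density_field(vals, domain, day = obs$day)
  attr(field, "mm_removed") <- er1$mm_removed
  attr(field, "eroded_r_t1gd") <- r1
  attr(field, "eroded_r_t2") <- r2
  field
}
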