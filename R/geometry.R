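#' Spherically-equivalent radius of a binary mask
#'
#' The SE radius is the radius of the sphere whose volume equals the
#' segmented volume: `(3V / 4 pi)^(1/3)` with `V` the number of TRUE voxels
#' times the voxel volume. It reduces an irregular 3D tumour volume to a
#' single length scale and is the quantity the growth curve and the Days
#' Gained score are expressed in.
#'
#' @param mask 3D logical (or 0/1) array.
#' @param spacing Numeric length-3 voxel size in mm.
#' @return SE radius in mm (0 for an empty mask).
#' @examples
#' m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
#' se_radius(m, c(1, 1, 1)) # (3 / (4*pi))^(1/3)
#' @export
se_radius <- function(mask, spacing = c(1, 1, 1)) {
  mask <- as_mask(mask, "mask")
  if (length(spacing) != 3 || any(spacing <= 0)) {
    stop_dimension("`spacing` must be three positive voxel sizes in mm.")
  }
  vol <- sum(mask) * prod(spacing)
  (3 * vol / (4 * pi))^(1 / 3)
}

# One 6-connected erosion pass (face-adjacent structuring element, so a
# single pass strips a one-voxel-thick perimeter layer).
erode_layer <- function(mask) {
  erode6_cpp(mask, as.integer(dim(mask)))
}

#' Erode a mask until its SE radius has shrunk by a fraction
#'
#' Iteratively strips the one-voxel perimeter (6-connected) from a tumour
#' mask and stops at the first iteration where the SE radius is at or below
#' `(1 - fraction)` of the original. This is how the simulation's initial
#' T1Gd region is carved out of the second pre-treatment segmentation; the
#' default fraction of 0.2 removes 20% of the SE radius.
#'
#' @param mask Non-empty 3D binary array.
#' @param spacing Voxel size in mm.
#' @param fraction Fraction of SE radius to remove, in (0, 1).
#' @param partial If the mask would empty before the target is reached:
#'   `FALSE` (default) raises a degenerate-tumour error; `TRUE` returns the
#'   last non-empty mask with a warning, so a pipeline can proceed on very
#'   small tumours.
#' @return A list with `mask` (eroded), `mm_removed` (SE-radius reduction
#'   actually achieved, mm), and `iterations`.
#' @seealso [erode_by_millimeters()] for the absolute-target variant applied
#'   to the T2 mask.
#' @export
erode_by_radius_fraction <- function(mask, spacing = c(1, 1, 1), fraction = 0.2,
                                     partial = FALSE) {
  mask <- as_mask(mask, "mask")
  if (!any(mask)) stop_degenerate("Cannot erode an empty mask.")
  if (length(fraction) != 1 || !is.finite(fraction) || fraction <= 0 || fraction >= 1) {
    stop_config("`fraction` must lie strictly between 0 and 1.")
  }
  r0 <- se_radius(mask, spacing)
  erode_to_target(mask, spacing, target = (1 - fraction) * r0, r0 = r0,
                  partial = partial)
}

#' Erode a mask until its SE radius has shrunk by a length in mm
#'
#' Same iterative perimeter stripping as [erode_by_radius_fraction()] but the
#' stopping criterion is an absolute SE-radius reduction. The pipeline uses
#' it on the T2 mask with the millimetres actually removed from the T1Gd
#' mask, so both imageable regions recede by the same physical margin.
#'
#' @inheritParams erode_by_radius_fraction
#' @param mm_target SE-radius reduction in mm (0 returns the mask unchanged).
#' @return As [erode_by_radius_fraction()].
#' @export
erode_by_millimeters <- function(mask, spacing = c(1, 1, 1), mm_target,
                                 partial = FALSE) {
  mask <- as_mask(mask, "mask")
  if (!any(mask)) stop_degenerate("Cannot erode an empty mask.")
  if (length(mm_target) != 1 || !is.finite(mm_target) || mm_target < 0) {
    stop_config("`mm_target` must be a single non-negative length in mm.")
  }
  r0 <- se_radius(mask, spacing)
  if (mm_target == 0) {
    return(list(mask = mask, mm_removed = 0, iterations = 0L))
  }
  if (mm_target >= r0) {
    stop_degenerate(sprintf(
      "Requested SE-radius reduction (%.2f mm) meets or exceeds the SE radius (%.2f mm).",
      mm_target, r0))
  }
  erode_to_target(mask, spacing, target = r0 - mm_target, r0 = r0,
                  partial = partial)
}

erode_to_target <- function(mask, spacing, target, r0, partial) {
  cur <- mask
  r <- r0
  it <- 0L
  while (r > target) {
    nxt <- erode_layer(cur)
    if (!any(nxt)) {
      msg <- sprintf(
        "Erosion emptied the mask after %d iteration(s) before reaching the target SE radius (%.2f mm).",
        it, target)
      if (!partial) stop_degenerate(msg)
      dg_warn(paste(msg, "Returning the last non-empty mask."),
              class = "dg_degenerate_warning")
      return(list(mask = cur, mm_removed = r0 - r, iterations = it))
    }
    cur <- nxt
    r <- se_radius(cur, spacing)
    it <- it + 1L
  }
  list(mask = cur, mm_removed = r0 - r, iterations = it)
}

#' Euclidean distance transform in millimetres
#'
#' Exact distance from every voxel centre to the nearest `TRUE` voxel centre,
#' honouring anisotropic voxel spacing. Used to build the Gaussian density
#' ramps of the initial condition from the eroded T1Gd/T2 surfaces.
#'
#' @param mask 3D logical array of feature voxels.
#' @param spacing Voxel size in mm.
#' @return 3D numeric array of distances (mm); `Inf` everywhere if the mask
#'   is empty, 0 on feature voxels.
#' @export
distance_transform <- function(mask, spacing = c(1, 1, 1)) {
  mask <- as_mask(mask, "mask")
  if (length(spacing) != 3 || any(spacing <= 0)) {
    stop_dimension("`spacing` must be three positive voxel sizes in mm.")
  }
  edt_mm_cpp(mask, as.integer(dim(mask)), as.numeric(spacing))
}
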