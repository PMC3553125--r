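#' Brain simulation domain
#'
#' A `brain_domain` bundles the voxel grid on which all masks and density
#' fields live: the grid shape, the voxel spacing in mm, and the binary brain
#' mask that confines tumour diffusion. All tumour masks attached to a domain
#' must live on the same grid; image registration is a precondition, not a
#' feature of this package.
#'
#' @param brain_mask 3D logical (or 0/1) array; `TRUE` marks brain tissue.
#' @param spacing Numeric length-3, mm per voxel along each axis (all > 0).
#' @param affine Optional 4x4 voxel-to-world matrix, carried through I/O only.
#'
#' @return An object of class `brain_domain` with fields `shape`, `spacing`,
#'   `brain_mask`, `affine`.
#' @examples
#' dom <- brain_domain(array(TRUE, c(8, 8, 8)), spacing = c(1, 1, 1))
#' dom$shape
#' @export
brain_domain <- function(brain_mask, spacing = c(1, 1, 1), affine = NULL) {
  mask <- as_mask(brain_mask, "brain_mask")
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop_config("`spacing` must be three positive voxel sizes in mm.")
  }
  if (!any(mask)) {
    stop_config("`brain_mask` has no TRUE voxel; an empty domain cannot host a tumour.")
  }
  if (!is.null(affine)) {
    if (!is.matrix(affine) || !all(dim(affine) == c(4, 4))) {
      stop_config("`affine` must be a 4x4 matrix.")
    }
  }
  structure(
    list(shape = dim(mask), spacing = as.numeric(spacing),
         brain_mask = mask, affine = affine),
    class = "brain_domain"
  )
}

#' Paired T1Gd/T2 tumour observation
#'
#' One MRI observation: the gadolinium-enhancing core segmented on T1Gd and
#' the larger T2/FLAIR abnormality, as co-registered binary masks, with the
#' acquisition day on the patient's own clock. The enhancing core must lie
#' within the T2 abnormality; voxels violating this are reported and the T2
#' mask is replaced by the union.
#'
#' @param t1gd_mask,t2_mask 3D logical (or 0/1) arrays on a common grid.
#' @param day Acquisition time in days (patient-relative, finite).
#' @param domain Optional [brain_domain()]; if given, both masks are checked
#'   against the grid and clipped to the brain mask (violations reported).
#'
#' @return An object of class `tumor_observation` with fields `t1gd_mask`,
#'   `t2_mask`, `day`.
#' @export
tumor_observation <- function(t1gd_mask, t2_mask, day, domain = NULL) {
  t1 <- as_mask(t1gd_mask, "t1gd_mask")
  t2 <- as_mask(t2_mask, "t2_mask")
  if (!identical(dim(t1), dim(t2))) {
    stop_dimension(sprintf(
      "T1Gd grid [%s] and T2 grid [%s] differ; masks must be co-registered.",
      paste(dim(t1), collapse = "x"), paste(dim(t2), collapse = "x")))
  }
  if (length(day) != 1 || !is.finite(day)) {
    stop_validation("`day` must be a single finite number of days.")
  }
  if (!is.null(domain)) {
    check_same_grid(dim(t1), domain$shape, "tumour mask")
    out1 <- sum(t1 & !domain$brain_mask)
    out2 <- sum(t2 & !domain$brain_mask)
    if (out1 + out2 > 0) {
      dg_warn(sprintf(
        "%d T1Gd and %d T2 voxels fall outside the brain mask; clipping.",
        out1, out2), class = "dg_mask_clipped")
      t1 <- t1 & domain$brain_mask
      t2 <- t2 & domain$brain_mask
    }
  }
  stray <- sum(t1 & !t2)
  if (stray > 0) {
    dg_warn(sprintf(
      "%d T1Gd voxels lie outside the T2 abnormality; replacing T2 by the union.",
      stray), class = "dg_mask_union")
    t2 <- t1 | t2
  }
  structure(list(t1gd_mask = t1, t2_mask = t2, day = as.numeric(day)),
            class = "tumor_observation")
}

# Coerce numeric/integer/logical arrays to a 3D logical mask.
as_mask <- function(x, what) {
  if (is.null(dim(x)) || length(dim(x)) != 3) {
    stop_dimension(sprintf("`%s` must be a 3D array.", what))
  }
  if (is.logical(x)) {
    storage.mode(x) <- "logical"
    if (anyNA(x)) stop_validation(sprintf("`%s` contains NA voxels.", what))
    return(x)
  }
  v <- as.numeric(x)
  if (anyNA(v)) stop_validation(sprintf("`%s` contains NA voxels.", what))
  if (!all(v %in% c(0, 1))) {
    stop_validation(sprintf("`%s` must be binary (0/1 or logical).", what))
  }
  array(v == 1, dim = dim(x))
}

check_same_grid <- function(got, want, what) {
  if (!identical(as.integer(got), as.integer(want))) {
    stop_dimension(sprintf("%s grid [%s] does not match domain grid [%s].",
                           what, paste(got, collapse = "x"),
                           paste(want, collapse = "x")))
  }
}

#' @export
print.brain_domain <- function(x, ...) {
  cat(sprintf("<brain_domain> %s voxels @ %s mm, %d brain voxels (%.1f cm^3)\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing, trim = TRUE), collapse = "x"),
              sum(x$brain_mask),
              sum(x$brain_mask) * prod(x$spacing) / 1000))
  invisible(x)
}

#' @export
print.tumor_observation <- function(x, ...) {
  cat(sprintf("<tumor_observation> day %.1f: %d T1Gd voxels, %d T2 voxels\n",
              x$day, sum(x$t1gd_mask), sum(x$t2_mask)))
  invisible(x)
}
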