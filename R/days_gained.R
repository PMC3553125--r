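#' Days Gained treatment-response score
#'
#' Scores an observed post-treatment tumour size against the untreated
#' virtual control's growth curve. The matched time is where the
#' piecewise-linear T1Gd SE-radius curve crosses the observed post-treatment
#' radius (earliest crossing if the curve is non-monotone); the score is the
#' post-treatment time minus the matched time — the number of days the
#' therapy delayed imageable progression. If the observed radius lies below
#' the curve's first sample or above its last, the matched time is
#' extrapolated along the chord through the curve's first and last points
#' (the linear radial expansion the model predicts), so a tumour smaller
#' than the curve's start yields a score exceeding the elapsed time and a
#' tumour larger than the untreated prediction yields a negative score.
#'
#' @param curve A `growth_curve` whose `time` axis contains `t_post` (same
#'   clock as `t_post`, typically patient-relative days).
#' @param r_post Observed post-treatment T1Gd SE radius in mm.
#' @param t_post Post-treatment time in days on the curve's clock.
#' @return An object of class `days_gained_score` with fields `score`,
#'   `matched_time`, `method` (`"interpolated_on_curve"` or
#'   `"chord_extrapolated"`), `modality` (`"T1Gd"`), `r_post`, `t_post`.
#' @examples
#' curve <- daysgained:::new_growth_curve(
#'   tibble::tibble(time = 0:100, r_t1gd = 10 + 0.1 * (0:100),
#'                  r_t2 = 12 + 0.1 * (0:100), total_cells = NA_real_),
#'   params = kinetic_parameters(0.1, 0.025),
#'   thresholds = detection_thresholds())
#' days_gained(curve, r_post = 12, t_post = 100)$score # 80
#' @export
days_gained <- function(curve, r_post, t_post) {
  stopifnot(inherits(curve, "growth_curve") || is.data.frame(curve))
  if (!all(c("time", "r_t1gd") %in% names(curve))) {
    stop_validation("`curve` needs columns `time` and `r_t1gd`.")
  }
  if (length(r_post) != 1 || !is.finite(r_post) || r_post < 0) {
    stop_validation("`r_post` must be a single non-negative radius in mm.")
  }
  tms <- curve$time
  r <- curve$r_t1gd
  if (is.unsorted(tms, strictly = TRUE)) {
    stop_validation("Curve times must be strictly increasing.")
  }
  if (t_post > max(tms) + 1e-9 || t_post < min(tms) - 1e-9) {
    stop_validation(sprintf(
      "t_post (%.1f) lies outside the curve's time span [%.1f, %.1f].",
      t_post, min(tms), max(tms)))
  }

  n <- length(r)
  if (n == 1 && abs(r_post - r) < 1e-12) {
    return(structure(list(score = t_post - tms, matched_time = tms,
                          method = "interpolated_on_curve", modality = "T1Gd",
                          r_post = r_post, t_post = t_post),
                     class = "days_gained_score"))
  }
  if (n > 1 && r_post >= min(r) && r_post <= max(r)) {
    sgn <- r - r_post
    idx <- which(sgn[-n] * sgn[-1] <= 0)[1] # earliest bracketing pair
    if (abs(sgn[idx]) < 1e-12) {
      t_star <- tms[idx]
    } else if (abs(r[idx + 1] - r[idx]) < 1e-12) {
      t_star <- tms[idx] # flat segment exactly at r_post
    } else {
      t_star <- tms[idx] + (r_post - r[idx]) / (r[idx + 1] - r[idx]) *
        (tms[idx + 1] - tms[idx])
    }
    method <- "interpolated_on_curve"
  } else {
    if (abs(r[n] - r[1]) < 1e-12) {
      stop_undefined_score(
        "Curve is flat between its endpoints; an out-of-range radius cannot be matched by chord extrapolation.")
    }
    t_star <- tms[1] + (r_post - r[1]) / (r[n] - r[1]) * (tms[n] - tms[1])
    method <- "chord_extrapolated"
  }

  structure(list(score = t_post - t_star, matched_time = t_star,
                 method = method, modality = "T1Gd",
                 r_post = r_post, t_post = t_post),
            class = "days_gained_score")
}

#' @export
print.days_gained_score <- function(x, ...) {
  cat(sprintf(
    "<days_gained_score> %.1f days (matched t = %.1f, r_post = %.2f mm, %s)\n",
    x$score, x$matched_time, x$r_post, x$method))
  invisible(x)
}

#' @rdname days_gained
#' @param x A `days_gained_score`.
#' @param ... Unused.
#' @export
tidy.days_gained_score <- function(x, ...) {
  tibble::tibble(score = x$score, matched_time = x$matched_time,
                 t_post = x$t_post, r_post = x$r_post,
                 method = x$method, modality = x$modality)
}
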