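#' Plot a simulated growth curve
#'
#' T1Gd and T2 spherically-equivalent radii against time.
#'
#' @param object A `growth_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.growth_curve <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("r_t1gd", "r_t2"), names_to = "modality",
                        values_to = "radius") |>
    dplyr::mutate(modality = dplyr::recode(.data$modality,
                                           r_t1gd = "T1Gd", r_t2 = "T2"))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$radius,
                                   colour = .data$modality)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "time (days)", y = "SE radius (mm)",
                  colour = NULL,
                  title = "Untreated virtual control growth curve") +
    ggplot2::theme_minimal()
}

#' Plot a threshold-scan p-value map
#'
#' Log-rank p-value against candidate Days Gained threshold, with the
#' admissibility constraint and the selected optimum marked; the linear
#' analogue of the p-value colour map.
#'
#' @param object A `threshold_scan`.
#' @param alpha Significance level drawn as a reference line (default 0.05).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.threshold_scan <- function(object, alpha = 0.05, ...) {
  df <- tibble::as_tibble(object)
  opt <- attr(object, "optimal_threshold")
  p <- ggplot2::ggplot(df[df$admissible, ],
                       ggplot2::aes(.data$threshold, .data$p_value)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_hline(yintercept = alpha, linetype = 2, colour = "red3") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Days Gained threshold (days)",
                  y = "log-rank p (log scale)",
                  title = "Constrained Kaplan-Meier threshold scan") +
    ggplot2::theme_minimal()
  if (!is.na(opt)) {
    p <- p + ggplot2::geom_vline(xintercept = opt, linetype = 3,
                                 colour = "blue3")
  }
  p
}

#' Plot a Kaplan-Meier curve
#'
#' @param object A `km_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df0 <- dplyr::bind_rows(tibble::tibble(time = 0, surv = 1), df)
  ggplot2::ggplot(df0, ggplot2::aes(.data$time, .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "survival probability",
                  title = "Kaplan-Meier estimate") +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of a cell-density field
#'
#' @param object A `cell_density_field`.
#' @param slice Axial (third-axis) slice index; default the middle slice.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cell_density_field <- function(object, slice = NULL, ...) {
  shp <- object$domain$shape
  slice <- slice %||% ceiling(shp[3] / 2)
  sl <- object$values[, , slice]
  df <- tidyr::expand_grid(y = seq_len(shp[2]), x = seq_len(shp[1]))
  df$density <- as.vector(sl)
  df$brain <- as.vector(object$domain$brain_mask[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$density)) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed(ratio = object$domain$spacing[2] /
                           object$domain$spacing[1]) +
    ggplot2::labs(title = sprintf("Normalised cell density, day %.0f (slice %d)",
                                  object$day, slice)) +
    ggplot2::theme_void()
}
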