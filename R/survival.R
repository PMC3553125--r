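#' Validate a tibble of survival records
#'
#' A survival cohort is a data frame with one row per patient per endpoint:
#' `patient_id`, `days_gained` (score in days), `time_to_event` (days,
#' non-negative), `event_observed` (logical; `FALSE` means censored at last
#' follow-up) and `endpoint` (`"PFS"` or `"OS"`). The PFS clock runs from
#' the start of cytotoxic therapy and the OS clock from diagnosis; supplying
#' times on the right clock is the caller's contract.
#'
#' @param records A data frame.
#' @return The validated tibble (invisibly usable in pipes).
#' @export
validate_survival_records <- function(records) {
  need <- c("patient_id", "days_gained", "time_to_event", "event_observed",
            "endpoint")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop_validation(paste0("Cohort table is missing column(s): ",
                           paste(missing_cols, collapse = ", "), "."))
  }
  bad <- which(!is.finite(records$time_to_event) | records$time_to_event < 0)
  if (length(bad)) {
    stop_validation(sprintf(
      "Row(s) %s have negative or non-finite time_to_event.",
      paste(head(bad, 10), collapse = ", ")))
  }
  bad <- which(!is.finite(records$days_gained))
  if (length(bad)) {
    stop_validation(sprintf("Row(s) %s have non-finite days_gained.",
                            paste(head(bad, 10), collapse = ", ")))
  }
  dup <- records |>
    dplyr::count(.data$patient_id, .data$endpoint) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    stop_validation(sprintf(
      "Duplicate patient/endpoint rows: %s.",
      paste(utils::head(paste0(dup$patient_id, "/", dup$endpoint), 5),
            collapse = ", ")))
  }
  tibble::as_tibble(records)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function for a set of
#' right-censored records, via `survival::survfit()`. The curve is 1 before
#' the first event and drops only at observed events; an all-censored cohort
#' yields a curve that never drops and is flagged with a warning.
#'
#' @param records Survival records (see [validate_survival_records()]).
#' @return A tibble of class `km_curve` with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`; the underlying `survfit` object is
#'   attached as attribute `fit`.
#' @export
km_curve <- function(records) {
  records <- validate_survival_records(records)
  if (nrow(records) == 0) stop_validation("No survival records supplied.")
  fit <- survival::survfit(
    survival::Surv(time_to_event, event_observed) ~ 1, data = records)
  out <- tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                        n_event = fit$n.event, n_censor = fit$n.censor,
                        surv = fit$surv)
  if (all(!records$event_observed)) {
    dg_warn("All observations are censored; the survival curve never drops.",
            class = "dg_all_censored")
  }
  structure(out, class = c("km_curve", class(out)), fit = fit)
}

#' Two-group log-rank test
#'
#' Standard two-group log-rank statistic (1 df chi-square) comparing the
#' survival experience of two sets of records, via `survival::survdiff()`.
#' A group with no events still contributes through the risk sets.
#'
#' @param group_a,group_b Survival records for the two groups.
#' @return A list with `chi_square`, `p_value`, `n` (per-group sizes) and
#'   `observed`/`expected` event counts per group.
#' @export
logrank <- function(group_a, group_b) {
  group_a <- validate_survival_records(group_a)
  group_b <- validate_survival_records(group_b)
  if (nrow(group_a) == 0 || nrow(group_b) == 0) {
    stop_validation("Both groups must be non-empty.")
  }
  dat <- dplyr::bind_rows(
    dplyr::mutate(group_a, .grp = "A"),
    dplyr::mutate(group_b, .grp = "B"))
  if (sum(dat$event_observed) == 0) {
    # no events anywhere: curves identical by construction
    return(list(chi_square = 0, p_value = 1,
                n = c(A = nrow(group_a), B = nrow(group_b)),
                observed = c(A = 0, B = 0), expected = c(A = 0, B = 0)))
  }
  sd <- survival::survdiff(
    survival::Surv(time_to_event, event_observed) ~ .grp, data = dat)
  chi <- unname(sd$chisq)
  list(chi_square = chi,
       p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
       n = stats::setNames(as.numeric(sd$n), c("A", "B")),
       observed = stats::setNames(as.numeric(sd$obs), c("A", "B")),
       expected = stats::setNames(as.numeric(sd$exp), c("A", "B")))
}

#' Constrained threshold scan over Days Gained scores
#'
#' The iterative Kaplan-Meier analysis used to find the Days Gained cutpoint
#' that best discriminates survival: for every candidate threshold the
#' cohort is split into scores below versus at-or-above the threshold, the
#' split is admissible only if both groups contain at least `min_fraction`
#' of the cohort (default 20%), and the two-group log-rank p-value is
#' computed for each admissible split. The optimal threshold is the
#' admissible one with the smallest p (ties broken toward the smallest
#' threshold). No multiple-testing correction is applied; the full p-map is
#' returned so the selection landscape is visible.
#'
#' @param records Survival records for one endpoint.
#' @param min_fraction Minimum fraction of patients on each side (default
#'   0.20).
#' @param grid Candidate thresholds in days; default every integer day
#'   between the smallest and largest observed score.
#' @return A tibble of class `threshold_scan` with columns `threshold`,
#'   `n_below`, `n_above`, `frac_below`, `frac_above`, `admissible`,
#'   `chi_square`, `p_value`; attributes `optimal_threshold`, `optimal_p`,
#'   `min_fraction`, `n`. With no admissible threshold the optimum is `NA`
#'   and a warning is raised.
#' @export
threshold_scan <- function(records, min_fraction = 0.20, grid = NULL) {
  records <- validate_survival_records(records)
  if (nrow(records) < 5) {
    stop_validation("At least 5 records are required for a threshold scan.")
  }
  if (length(unique(records$endpoint)) > 1) {
    stop_validation("Scan one endpoint at a time; filter `endpoint` first.")
  }
  if (min_fraction <= 0 || min_fraction > 0.5) {
    stop_config("`min_fraction` must lie in (0, 0.5].")
  }
  if (is.null(grid)) {
    grid <- seq(ceiling(min(records$days_gained)),
                floor(max(records$days_gained)), by = 1)
  }
  if (length(grid) == 0) stop_config("Empty threshold grid.")
  grid <- sort(unique(grid))
  n <- nrow(records)

  # thresholds falling between the same adjacent observed scores induce the
  # same split, so each unique partition is tested once
  n_above_all <- vapply(grid, function(thr) sum(records$days_gained >= thr),
                        integer(1))
  adm_all <- (n - n_above_all) / n >= min_fraction &
    n_above_all / n >= min_fraction
  stats_for <- new.env(parent = emptyenv())
  scan <- purrr::map_dfr(seq_along(grid), function(i) {
    thr <- grid[i]
    n_above <- n_above_all[i]
    n_below <- n - n_above
    adm <- adm_all[i]
    chi <- p <- NA_real_
    if (adm) {
      key <- as.character(n_above)
      cached <- stats_for[[key]]
      if (is.null(cached)) {
        hi <- records$days_gained >= thr
        lr <- logrank(records[!hi, , drop = FALSE], records[hi, , drop = FALSE])
        cached <- c(lr$chi_square, lr$p_value)
        stats_for[[key]] <- cached
      }
      chi <- cached[1]
      p <- cached[2]
    }
    tibble::tibble(threshold = thr, n_below = n_below, n_above = n_above,
                   frac_below = n_below / n, frac_above = n_above / n,
                   admissible = adm, chi_square = chi, p_value = p)
  })

  opt_thr <- opt_p <- NA_real_
  adm <- scan[scan$admissible & !is.na(scan$p_value), , drop = FALSE]
  if (nrow(adm) == 0) {
    dg_warn("No admissible threshold under the group-size constraint.",
            class = "dg_no_admissible_threshold")
  } else {
    best <- which.min(adm$p_value) # which.min takes the first = smallest threshold
    opt_thr <- adm$threshold[best]
    opt_p <- adm$p_value[best]
  }
  structure(scan, class = c("threshold_scan", class(scan)),
            optimal_threshold = opt_thr, optimal_p = opt_p,
            min_fraction = min_fraction, n = n,
            endpoint = unique(records$endpoint))
}

#' @rdname threshold_scan
#' @param x A `threshold_scan`.
#' @param ... Unused.
#' @export
tidy.threshold_scan <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname threshold_scan
#' @export
glance.threshold_scan <- function(x, ...) {
  tibble::tibble(optimal_threshold = attr(x, "optimal_threshold"),
                 optimal_p = attr(x, "optimal_p"),
                 n = attr(x, "n"),
                 min_fraction = attr(x, "min_fraction"),
                 n_admissible = sum(x$admissible),
                 endpoint = attr(x, "endpoint") %||% NA_character_)
}
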