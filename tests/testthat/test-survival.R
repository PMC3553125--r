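records <- function(time, event, dg = NULL, endpoint = "OS") {
  n <- length(time)
  tibble::tibble(patient_id = sprintf("P%02d", seq_len(n)),
                 days_gained = dg %||% rep(0, n),
                 time_to_event = time,
                 event_observed = event,
                 endpoint = endpoint)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the product-limit curve matches hand computation", {
  # n = 2, events at 10 and 20
  km <- km_curve(records(c(10, 20), c(TRUE, TRUE)))
  expect_equal(km$surv[km$time == 10], 0.5)
  expect_equal(km$surv[km$time == 20], 0)

  # n = 4: events at 5, 10; censored at 7, 12. Risk sets 4 then 2:
  # S(5+) = 3/4, S(10+) = 3/4 * 1/2 = 0.375
  km2 <- km_curve(records(c(5, 7, 10, 12), c(TRUE, FALSE, TRUE, FALSE)))
  expect_equal(km2$surv[km2$time == 5], 0.75)
  expect_equal(km2$surv[km2$time == 10], 0.375)

  # curve is a proper survival function
  expect_true(all(diff(km2$surv) <= 0))
  expect_true(all(km2$surv >= 0 & km2$surv <= 1))
})

test_that("an all-censored cohort yields a flat, flagged curve", {
  expect_warning(km <- km_curve(records(c(3, 8, 12), rep(FALSE, 3))),
                 class = "dg_all_censored")
  expect_true(all(km$surv == 1))
})

test_that("log-rank of a group against its duplicate is exactly null", {
  g <- records(c(5, 9, 14, 20), c(TRUE, TRUE, FALSE, TRUE))
  lr <- logrank(g, g)
  expect_equal(lr$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)
})

test_that("log-rank matches the brute-force risk-set oracle", {
  set.seed(23)
  for (rep in 1:5) {
    ta <- round(stats::rexp(10, 1 / 100)) + 1
    tb <- round(stats::rexp(10, 1 / 60)) + 1
    ea <- stats::runif(10) < 0.8
    eb <- stats::runif(10) < 0.8
    lr <- logrank(records(ta, ea), records(tb, eb))
    oracle <- logrank_oracle(ta, ea, tb, eb)
    expect_equal(lr$chi_square, oracle$chi_square, tolerance = 1e-6)
    expect_equal(lr$p_value, oracle$p_value, tolerance = 1e-6)
  }
})

test_that("one patient per group with distinct event times gives chi = 1", {
  # risk table at the first event: 1 observed, 1/2 expected, variance 1/4;
  # the second event has a single patient at risk and contributes nothing
  lr <- logrank(records(5, TRUE), records(9, TRUE))
  expect_equal(lr$chi_square, 1, tolerance = 1e-12)
  oracle <- logrank_oracle(5, TRUE, 9, TRUE)
  expect_equal(lr$chi_square, oracle$chi_square, tolerance = 1e-12)
})

test_that("log-rank is symmetric in group labels", {
  a <- records(c(5, 9, 14), c(TRUE, TRUE, FALSE))
  b <- records(c(4, 11, 30, 33), c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(logrank(a, b)$chi_square, logrank(b, a)$chi_square,
               tolerance = 1e-12)
  # and invariant under a common rescaling of the clock
  a2 <- a; a2$time_to_event <- a2$time_to_event * 7
  b2 <- b; b2$time_to_event <- b2$time_to_event * 7
  expect_equal(logrank(a, b)$chi_square, logrank(a2, b2)$chi_square,
               tolerance = 1e-12)
})

test_that("threshold admissibility is exactly the group-fraction rule", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(20:60, 1)
    co <- make_survival_cohort(n, hazard_ratio = 1, seed = rep)
    mf <- sample(c(0.1, 0.2, 0.3), 1)
    scan <- threshold_scan(co, min_fraction = mf)
    n_above <- vapply(scan$threshold,
                      function(th) sum(co$days_gained >= th), integer(1))
    expect_identical(scan$admissible,
                     (n - n_above) / n >= mf & n_above / n >= mf)
    expect_true(all(is.na(scan$p_value[!scan$admissible])))
    expect_true(all(!is.na(scan$p_value[scan$admissible])))
  }
})

test_that("min_fraction = 0.5 with 10 records admits only the median split", {
  co <- records(time = seq(10, 100, by = 10), event = rep(TRUE, 10),
                dg = 1:10)
  scan <- threshold_scan(co, min_fraction = 0.5)
  expect_identical(scan$threshold[scan$admissible], 6)
})

test_that("ties in p go to the smallest threshold", {
  # scores with a gap: thresholds 3..5 induce the same partition
  co <- records(time = c(5, 8, 12, 30, 40, 45, 60, 80),
                event = rep(TRUE, 8),
                dg = c(1, 1, 2, 2, 5, 6, 7, 8))
  scan <- threshold_scan(co, min_fraction = 0.25, grid = 2:8)
  adm <- scan[scan$admissible, ]
  best_p <- min(adm$p_value)
  expect_equal(attr(scan, "optimal_threshold"),
               min(adm$threshold[adm$p_value == best_p]))
})

test_that("scan warns when no threshold satisfies the constraint", {
  co <- records(time = c(10, 20, 30, 40, 50), event = rep(TRUE, 5),
                dg = c(1, 1, 1, 1, 1))
  expect_warning(scan <- threshold_scan(co, grid = 0:2),
                 class = "dg_no_admissible_threshold")
  expect_true(is.na(attr(scan, "optimal_threshold")))
})

test_that("cohort validation reports offending rows", {
  co <- records(c(10, -5, 20), c(TRUE, TRUE, FALSE))
  expect_error(validate_survival_records(co), class = "dg_validation_error",
               regexp = "2")
  dup <- records(c(10, 20), c(TRUE, TRUE))
  dup$patient_id <- c("P01", "P01")
  expect_error(validate_survival_records(dup), class = "dg_validation_error",
               regexp = "P01")
  expect_error(validate_survival_records(co[, -2]),
               class = "dg_validation_error", regexp = "days_gained")
})

test_that("tidy and glance expose the scan results", {
  co <- make_survival_cohort(40, seed = 3)
  scan <- threshold_scan(co)
  td <- tidy(scan)
  expect_s3_class(td, "tbl_df")
  g <- glance(scan)
  expect_identical(g$n, 40L)
  expect_true(g$optimal_threshold %in% td$threshold)
  expect_equal(g$optimal_p, min(td$p_value[td$admissible]))
})
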