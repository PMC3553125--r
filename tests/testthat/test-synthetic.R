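test_that("synthetic brain geometries have the expected volume and topology", {
  dom <- make_brain_domain(c(64, 64, 64))
  # radius-30 ball at 1 mm
  expect_lt(abs(sum(dom$brain_mask) - 4 / 3 * pi * 30^3) / (4 / 3 * pi * 30^3),
            0.02)
  lob <- make_brain_domain(c(48, 48, 48), geometry = "two_lobe")
  expect_true(mask_connected(lob$brain_mask))
  # constriction: midline cross-section is smaller than the lobe centres'
  mid <- sum(lob$brain_mask[24, , ])
  lobe <- sum(lob$brain_mask[14, , ])
  expect_lt(mid, lobe)
  ell <- make_brain_domain(c(48, 40, 32), geometry = "ellipsoid")
  expect_true(any(ell$brain_mask))
  expect_error(make_brain_domain(c(8, 8, 8)), class = "dg_config_error")
})

test_that("virtual patients are reproducible and satisfy the mask invariants", {
  dom <- make_brain_domain(c(48, 48, 48))
  vp1 <- make_virtual_patient(days = c(20, 30, 45), domain = dom,
                              seed_radius = 6, noise_prob = 0.2, seed = 9)
  vp2 <- make_virtual_patient(days = c(20, 30, 45), domain = dom,
                              seed_radius = 6, noise_prob = 0.2, seed = 9)
  expect_identical(vp1$pre1$t1gd_mask, vp2$pre1$t1gd_mask)
  expect_identical(vp1$post$t2_mask, vp2$post$t2_mask)
  vp3 <- make_virtual_patient(days = c(20, 30, 45), domain = dom,
                              seed_radius = 6, noise_prob = 0.2, seed = 10)
  expect_false(identical(vp1$pre1$t1gd_mask, vp3$pre1$t1gd_mask))

  for (ob in list(vp1$pre1, vp1$pre2, vp1$post)) {
    expect_true(all(ob$t2_mask[ob$t1gd_mask]))          # T1Gd inside T2
    expect_true(all(dom$brain_mask[ob$t2_mask]))        # inside the brain
  }
  # tumour grows between the pre-treatment scans
  expect_gt(sum(vp1$pre2$t1gd_mask), sum(vp1$pre1$t1gd_mask))
})

test_that("virtual patient timing rules are enforced", {
  dom <- make_brain_domain(c(48, 48, 48))
  expect_error(make_virtual_patient(days = c(30, 33, 60), domain = dom),
               class = "dg_interval_error")
  expect_error(make_virtual_patient(days = c(30, 20, 60), domain = dom),
               class = "dg_config_error")
  expect_error(make_virtual_patient(days = c(20, 30, 45), response_days = 50,
                                    domain = dom),
               class = "dg_config_error")
})

test_that("the planted response shifts the post observation back in time", {
  dom <- make_brain_domain(c(48, 48, 48))
  vp0 <- make_virtual_patient(days = c(20, 30, 45), domain = dom, seed_radius = 6)
  vp30 <- make_virtual_patient(days = c(20, 30, 45), response_days = 15,
                               domain = dom, seed_radius = 6)
  # treated tumour is smaller than the untreated one at the same scan day
  expect_lt(sum(vp30$post$t1gd_mask), sum(vp0$post$t1gd_mask))
  expect_equal(vp30$post$day, 45) # stamped with the scan day, not the shifted day
  # zero response: post mask equals the ground truth at t_post
  expect_identical(vp0$post$t1gd_mask,
                   curve_fields(vp0$true_curve)[["t45"]]$values >=
                     vp0$thresholds$t1gd_fraction)
})

test_that("survival cohorts respect their stated distribution and censoring", {
  co <- make_survival_cohort(500, censoring_rate = 0, seed = 4)
  expect_true(all(co$event_observed))
  expect_true(all(co$days_gained >= -77 & co$days_gained <= 512))
  expect_equal(mean(co$days_gained), 134, tolerance = 0.1)

  co2 <- make_survival_cohort(500, censoring_rate = 0.3, seed = 4)
  expect_equal(mean(!co2$event_observed), 0.3, tolerance = 0.25)
  expect_identical(co2, make_survival_cohort(500, censoring_rate = 0.3, seed = 4))

  expect_error(make_survival_cohort(5), class = "dg_config_error")
  expect_error(make_survival_cohort(50, hazard_ratio = 0), class = "dg_config_error")
  expect_error(make_survival_cohort(50, censoring_rate = 1), class = "dg_config_error")
})

test_that("a planted hazard drop is recovered by the threshold scan", {
  co <- make_survival_cohort(200, threshold = 100, hazard_ratio = 3, seed = 7)
  scan <- threshold_scan(co)
  expect_lt(abs(attr(scan, "optimal_threshold") - 100), 15)
  expect_lt(attr(scan, "optimal_p"), 0.001)
})

test_that("null cohorts give unremarkable scan optima reasonably often", {
  op <- vapply(1:12, function(s) {
    co <- make_survival_cohort(100, hazard_ratio = 1, seed = 4000 + s)
    attr(threshold_scan(co), "optimal_p")
  }, numeric(1))
  # selection makes the minimum p small, but under the null it should not
  # be uniformly extreme across seeds
  expect_gt(mean(op > 0.05), 0.05)
})

test_that("fixture directories are self-contained and internally consistent", {
  dir <- withr::local_tempdir()
  dom <- make_brain_domain(c(48, 48, 48))
  vp <- make_virtual_patient(days = c(20, 30, 45), domain = dom, seed_radius = 6)
  write_fixture_dir(dir, patient = vp, cohort = make_survival_cohort(30, seed = 2))
  files <- c("brain_mask.nii.gz", "pre1_t1gd.nii.gz", "pre1_t2.nii.gz",
             "pre2_t1gd.nii.gz", "pre2_t2.nii.gz", "post_t1gd.nii.gz",
             "post_t2.nii.gz", "cohort.csv", "manifest.json")
  expect_true(all(file.exists(file.path(dir, files))))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$true_D, vp$true_params$D)
  expect_equal(man$days$pre2, 30)
  back <- read_volume(file.path(dir, "pre2_t1gd.nii.gz"))
  expect_identical(back$values != 0, vp$pre2$t1gd_mask)
  co <- read_cohort_table(file.path(dir, "cohort.csv"))
  expect_equal(nrow(co), 30)
})
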