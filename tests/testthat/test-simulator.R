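test_that("pure diffusion conserves total cell mass under zero-flux walls", {
  dom <- brain_domain(rasterize_ball(c(33, 33, 33), radius = 15))
  thr <- default_thresholds
  seedf <- daysgained:::seed_field(dom, kinetic_parameters(0.2, 0.02), thr, 6)
  p <- kinetic_parameters(0.2, 0) # rho = 0: diffusion only
  m0 <- sum(seedf$values)
  out <- fkpp_step(seedf, p, dt = 0.5, nsteps = 60)
  expect_lt(abs(sum(out$values) - m0) / m0, 1e-8)
  expect_equal(attr(out, "clip_total"), 0)
})

test_that("the D = 0 limit reproduces logistic growth to 1e-3", {
  dom <- brain_domain(array(TRUE, c(4, 4, 4)))
  f <- cell_density_field(array(0.4, c(4, 4, 4)), dom)
  p <- kinetic_parameters(0, 0.05)
  out <- fkpp_step(f, p, dt = 0.1, nsteps = 200) # 20 days
  expected <- logistic_closed_form(0.4, 0.05, 20)
  expect_equal(expected, 0.6444, tolerance = 1e-4)
  expect_true(all(abs(out$values - expected) < 1e-3))
})

test_that("the zero field is a fixed point", {
  dom <- brain_domain(array(TRUE, c(6, 6, 6)))
  f <- cell_density_field(array(0, c(6, 6, 6)), dom)
  out <- fkpp_step(f, kinetic_parameters(0.1, 0.05), dt = 0.5, nsteps = 20)
  expect_true(all(out$values == 0))
})

test_that("stability violations are rejected before stepping", {
  dom <- brain_domain(array(TRUE, c(8, 8, 8)))
  f <- cell_density_field(array(0.1, c(8, 8, 8)), dom)
  p <- kinetic_parameters(1, 0.01) # bound = 1/(2*1*3) = 1/6 day
  expect_error(fkpp_step(f, p, dt = 0.5), class = "dg_stability_error")
  expect_error(
    simulate_uvc(f, p, sim_config(duration = 2, dt = 0.5)),
    class = "dg_stability_error")
})

test_that("simulated growth curves are deterministic and internally consistent", {
  dom <- make_brain_domain(c(48, 48, 48))
  thr <- default_thresholds
  p <- kinetic_parameters(0.05, 0.02)
  seedf <- daysgained:::seed_field(dom, p, thr, 7)
  cfg <- sim_config(duration = 20, sample_interval = 2)
  c1 <- simulate_uvc(seedf, p, cfg, thr)
  c2 <- simulate_uvc(seedf, p, cfg, thr)
  expect_identical(as.data.frame(c1), as.data.frame(c2)) # bitwise

  expect_true(all(diff(c1$time) > 0))
  expect_true(all(c1$r_t2 >= c1$r_t1gd))
  expect_true(all(c1$r_t1gd >= 0))
  # includes both endpoints
  expect_equal(c1$time[1], 0)
  expect_equal(c1$time[nrow(c1)], 20)
  # T1Gd radius non-decreasing after a 5-day burn-in (wave regime)
  late <- c1$r_t1gd[c1$time >= 5]
  expect_true(all(diff(late) >= 0))
})

test_that("a zero-duration simulation returns the initial measurements", {
  dom <- make_brain_domain(c(48, 48, 48))
  thr <- default_thresholds
  p <- kinetic_parameters(0.05, 0.02)
  seedf <- daysgained:::seed_field(dom, p, thr, 7)
  cv <- simulate_uvc(seedf, p, sim_config(duration = 0), thr)
  expect_equal(nrow(cv), 1)
  m <- daysgained:::measure_field(seedf$values, dom$spacing, thr)
  expect_equal(cv$r_t1gd, unname(m["r_t1gd"]))
  expect_equal(cv$total_cells, unname(m["total_cells"]))
})

test_that("density stays exactly zero outside a constricted brain mask", {
  dom <- make_brain_domain(c(48, 48, 48), geometry = "two_lobe")
  thr <- default_thresholds
  p <- kinetic_parameters(0.1, 0.03)
  ctr <- (dom$shape - 1) / 2 * dom$spacing
  off <- 0.22 * dom$shape[1] * dom$spacing[1]
  seedf <- daysgained:::seed_field(dom, p, thr, 5,
                                   center = ctr - c(off, 0, 0))
  cv <- simulate_uvc(seedf, p, sim_config(duration = 40, sample_interval = 40,
                                          store_fields = TRUE), thr)
  final <- curve_fields(cv)[["t40"]]
  expect_true(all(final$values[!dom$brain_mask] == 0))
  expect_gt(max(final$values[dom$brain_mask]), 0.5)
})

test_that("halving the grid spacing changes the final radius by < 5%", {
  thr <- default_thresholds
  p <- kinetic_parameters(0.05, 0.02)
  r_final <- vapply(list(c(64, 1), c(128, 0.5)), function(cfg) {
    dom <- make_brain_domain(rep(cfg[1], 3), rep(cfg[2], 3))
    seedf <- daysgained:::seed_field(dom, p, thr, 8)
    cv <- simulate_uvc(seedf, p, sim_config(duration = 30, sample_interval = 30), thr)
    cv$r_t1gd[nrow(cv)]
  }, numeric(1))
  expect_lt(abs(r_final[2] - r_final[1]) / r_final[1], 0.05)
})

test_that("sim_config validates its inputs", {
  expect_error(sim_config(duration = -1), class = "dg_config_error")
  expect_error(sim_config(duration = 10, dt = 0), class = "dg_config_error")
  expect_error(sim_config(duration = 10, sample_interval = 0),
               class = "dg_config_error")
  expect_error(sim_config(duration = 10, record_times = 12),
               class = "dg_config_error")
})
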