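test_that("radial velocity is the T1Gd secant, guarded by the 5-day minimum", {
  expect_equal(estimate_velocity(10, 15, 0, 50), 0.1)
  expect_error(estimate_velocity(10, 10, 0, 50), class = "dg_estimation_error")
  expect_error(estimate_velocity(10, 15, 0, 4), class = "dg_interval_error")
  expect_error(estimate_velocity(15, 10, 0, 30), class = "dg_estimation_error")
})

test_that("kinetic_parameters derives velocity and infiltration length", {
  p <- kinetic_parameters(0.1, 0.025)
  expect_equal(p$velocity, 2 * sqrt(0.1 * 0.025), tolerance = 1e-15)
  expect_equal(p$infiltration_length, 2)
  expect_error(kinetic_parameters(-1, 0.1), class = "dg_config_error")
  expect_error(kinetic_parameters(0, 0), class = "dg_config_error")
  td <- tidy(p)
  expect_identical(td$term, c("D", "rho", "velocity", "infiltration_length"))
})

test_that("front profile and margin constant match an independent integration", {
  prof <- front_profile()
  # frozen value from an independent scipy solve_ivp integration of
  # u'' + 2u' + u(1-u) = 0 shot from the u = 1 saddle: margin 6.10605
  expect_equal(front_margin_constant(0.80, 0.16), 6.10605, tolerance = 2e-4)
  # profile is a decreasing sigmoid with the right limits
  z <- seq(-10, 30, by = 0.5)
  u <- prof(z)
  expect_true(all(diff(u) <= 0))
  expect_gt(prof(-15), 0.99) # saturates exponentially toward 1
  expect_equal(prof(-80), 1)
  expect_lt(prof(40), 1e-9)
  expect_equal(prof(0), 0.5, tolerance = 1e-6)
  # wider contour pairs give wider margins
  expect_gt(front_margin_constant(0.9, 0.05), front_margin_constant(0.8, 0.16))
})

test_that("detection thresholds enforce their ordering", {
  expect_error(detection_thresholds(t1gd_fraction = 0.1, t2_fraction = 0.5),
               class = "dg_config_error")
  expect_error(detection_thresholds(carrying_capacity = -1),
               class = "dg_config_error")
})

make_obs_pair <- function(r1a, r1b, r2b, day_a, day_b, shape = c(61, 61, 61)) {
  t1a <- rasterize_ball(shape, radius = r1a)
  t2a <- rasterize_ball(shape, radius = r1a + (r2b - r1b))
  t1b <- rasterize_ball(shape, radius = r1b)
  t2b <- rasterize_ball(shape, radius = r2b)
  list(early = tumor_observation(t1a, t2a, day_a),
       late = tumor_observation(t1b, t2b, day_b))
}

test_that("parameter estimation inverts the travelling-wave relations", {
  obs <- make_obs_pair(10, 14, 24, 0, 40)
  thr <- detection_thresholds()
  # oracle: recompute the algebra from the measured SE radii
  r1 <- se_radius(obs$early$t1gd_mask)
  r2 <- se_radius(obs$late$t1gd_mask)
  dr <- se_radius(obs$late$t2_mask) - r2
  v <- (r2 - r1) / 40

  est <- estimate_parameters(obs$early, obs$late, thr)
  kappa <- front_margin_constant(0.80, 0.16)
  expect_equal(est$D, (v / 2) * dr / kappa, tolerance = 1e-12)
  expect_equal(est$rho, (v / 2) * kappa / dr, tolerance = 1e-12)
  expect_equal(2 * sqrt(est$D * est$rho), v, tolerance = 1e-12)

  # classical exponential-tail option: infiltration length = margin / ln 5
  est2 <- estimate_parameters(obs$early, obs$late, thr,
                              margin_rule = "exponential_tail")
  expect_equal(est2$D, (v / 2) * dr / log(5), tolerance = 1e-12)
  expect_equal(est2$rho, (v / 2) * log(5) / dr, tolerance = 1e-12)
})

test_that("the exponential-tail algebra reproduces the worked example", {
  # v = 0.2 mm/day, margin 10 mm, thresholds (0.80, 0.16):
  # D = 0.1 * 10 / ln 5, rho = 0.1 * ln 5 / 10, and 2 sqrt(D rho) = v
  D <- 0.1 * 10 / log(5)
  rho <- 0.1 * log(5) / 10
  expect_equal(D, 0.6213, tolerance = 1e-4)
  expect_equal(rho, 0.016094, tolerance = 1e-4)
  expect_equal(2 * sqrt(D * rho), 0.2, tolerance = 1e-12)
})

test_that("estimation scales consistently with the observation interval", {
  obs_fast <- make_obs_pair(10, 14, 24, 0, 20)
  obs_slow <- make_obs_pair(10, 14, 24, 0, 40)
  est_fast <- estimate_parameters(obs_fast$early, obs_fast$late)
  est_slow <- estimate_parameters(obs_slow$early, obs_slow$late)
  # same radii over twice the time: both rates halve, geometry unchanged
  expect_equal(est_slow$D, est_fast$D / 2, tolerance = 1e-12)
  expect_equal(est_slow$rho, est_fast$rho / 2, tolerance = 1e-12)
  expect_equal(est_slow$infiltration_length, est_fast$infiltration_length,
               tolerance = 1e-12)
})

test_that("margin source 'mean' averages the two observations' margins", {
  obs <- make_obs_pair(10, 14, 26, 0, 40) # early margin 12, late margin ~12
  est_late <- estimate_parameters(obs$early, obs$late, margin_source = "late")
  est_mean <- estimate_parameters(obs$early, obs$late, margin_source = "mean")
  m_late <- se_radius(obs$late$t2_mask) - se_radius(obs$late$t1gd_mask)
  m_early <- se_radius(obs$early$t2_mask) - se_radius(obs$early$t1gd_mask)
  expect_equal(est_mean$infiltration_length / est_late$infiltration_length,
               mean(c(m_late, m_early)) / m_late, tolerance = 1e-12)
})

test_that("a vanishing T2 margin is a margin error", {
  shape <- c(41, 41, 41)
  ball <- rasterize_ball(shape, radius = 10)
  small <- rasterize_ball(shape, radius = 8)
  obs_early <- tumor_observation(small, small, 0)
  obs_late <- tumor_observation(ball, ball, 30)
  expect_error(estimate_parameters(obs_early, obs_late),
               class = "dg_margin_error")
})
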