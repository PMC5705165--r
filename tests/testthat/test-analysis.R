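test_that("circle fitting recovers exact circles and rejects lines", {
  th <- seq(0, 1.8 * pi, length.out = 40)
  f <- fit_rotation_circle(0.5 * cos(th) + 2, 0.5 * sin(th) - 1)
  expect_equal(f$radius, 0.5, tolerance = 1e-10)
  expect_equal(f$center, c(2, -1), tolerance = 1e-10)
  expect_lt(f$rms, 1e-10)
  # collinear points prefer the line model
  f2 <- fit_rotation_circle(seq(0, 3, length.out = 30),
                            2 * seq(0, 3, length.out = 30) + 1)
  expect_identical(f2$radius, Inf)
  # noisy circle stays within 5% of the true radius
  set.seed(99)
  f3 <- fit_rotation_circle(0.8 * cos(th) + rnorm(40, 0, 0.01),
                            0.8 * sin(th) + rnorm(40, 0, 0.01))
  expect_equal(f3$radius, 0.8, tolerance = 0.05)
})

test_that("synthetic tracks classify into the three states", {
  expect_identical(classify_state(synthetic_track("stationary"))$state,
                   "stationary")
  expect_identical(classify_state(synthetic_track("translation",
                                                  speed = 1))$state,
                   "translation")
  lab <- classify_state(synthetic_track("rotation", speed = 1, radius = 0.8,
                                        area = pi))
  expect_identical(lab$state, "rotation")
  expect_equal(lab$radius, 0.8, tolerance = 0.02)
  # radius well above the cell size is a translation-like (curved) path
  lab2 <- classify_state(synthetic_track("rotation", speed = 1, radius = 6,
                                         area = pi))
  expect_identical(lab2$state, "translation")
})

test_that("classification is invariant under rigid motions of the track", {
  d <- synthetic_track("rotation", speed = 1.2, radius = 0.7, area = pi)
  phi <- 0.7
  d2 <- d
  d2$x <- cos(phi) * d$x - sin(phi) * d$y + 5
  d2$y <- sin(phi) * d$x + cos(phi) * d$y - 3
  l1 <- classify_state(d)
  l2 <- classify_state(d2)
  expect_identical(l1$state, l2$state)
  expect_equal(l1$radius, l2$radius, tolerance = 1e-8)
})

test_that("steady metrics satisfy the rotation kinematics identity", {
  r <- 0.9; T <- 4
  d <- synthetic_track("rotation", speed = 2 * pi * r / T, radius = r)
  m <- steady_metrics(d)
  expect_equal(m$angular_velocity, 2 * pi / T, tolerance = 0.01)
  expect_equal(m$speed, m$radius * m$angular_velocity, tolerance = 0.01)
  m2 <- steady_metrics(synthetic_track("translation", speed = 1.3))
  expect_identical(m2$angular_velocity, 0)
})

test_that("non-steady records raise an unresolved classification error", {
  d <- synthetic_track("translation", speed = 1, t_end = 20)
  d$speed <- d$speed * (1 + 0.5 * sin(d$t)) # persistent large modulation
  expect_error(classify_state(d), class = "actomotion_unresolved")
  expect_error(classify_state(d), "unresolved")
})

test_that("phase_scan handles empty and duplicate grids deterministically", {
  empty <- phase_scan("ZS", numeric(0), numeric(0),
                      settings = solver_settings(t_end = 1))
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("variant", "alpha", "v0", "mu_tot", "state", "speed",
                    "radius", "omega", "aspect_ratio", "area", "ambiguous")
                  %in% names(empty)))
  s <- solver_settings(h = 0.2, c = 0.025, t_end = 8)
  tab <- phase_scan("ZS", v0_values = c(2.5, 2.5),
                    mu_tot_values = 0.125 * pi, alpha_values = 0.5,
                    settings = s,
                    base = motility_params("ZS", g = 0.2))
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$state, "stationary")
})

test_that("scan results plot as a phase diagram", {
  tab <- tibble::tibble(variant = "ZS", alpha = 0.5, v0 = c(2.5, 5),
                        mu_tot = c(pi, 2 * pi),
                        state = c("translation", "rotation"),
                        speed = c(1, 2), radius = c(Inf, 1), omega = c(0, 2),
                        aspect_ratio = c(2, 1.8), area = c(3, 2.5),
                        ambiguous = c(FALSE, TRUE))
  class(tab) <- c("actomotion_scan", class(tab))
  pl <- ggplot2::autoplot(tab)
  expect_s3_class(pl, "ggplot")
})
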