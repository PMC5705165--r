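test_that("dispersion rate matches the analytic form and its limits", {
  # neutral exactly at the critical contractility for q = pi
  for (alpha in c(0.1, 0.5, 1, 2)) {
    beta <- 5
    mu_c <- critical_mu_tot(alpha, beta)
    expect_equal(dispersion_rate(pi, alpha, beta, mu_c), 0, tolerance = 1e-12)
    expect_gt(dispersion_rate(pi, alpha, beta, mu_c * 1.01), 0)
    expect_lt(dispersion_rate(pi, alpha, beta, mu_c * 0.99), 0)
  }
  # pure dissipation without contractility
  q <- pi * (1:4)
  expect_equal(dispersion_rate(q, 0.5, 5, 0), -q^2)
})

test_that("dispersion rate agrees with the finite-difference linearization", {
  lam <- dispersion_rate(pi, 0.5, 5, 2)
  expect_equal(lam, pi^2 * (10 / (1 + 0.5 * pi^2) - 1), tolerance = 1e-12)
  lam_fd <- oracle_dispersion_fd(0.5, 5, 2, n = 400)
  expect_equal(lam_fd, lam, tolerance = 0.01)
  # and across a small parameter grid (unstable cases)
  for (alpha in c(0.25, 1)) {
    for (mu in c(2.5, 4)) {
      expect_equal(oracle_dispersion_fd(alpha, 5, mu, n = 300),
                   max(dispersion_rate(pi * (1:6), alpha, 5, mu)),
                   tolerance = 0.02)
    }
  }
})

test_that("critical myosin load increases with the viscosity-adhesion length", {
  expect_equal(critical_mu_tot(0, 5), 1 / 5)
  expect_equal(critical_mu_tot(0.5, 5), (1 + pi^2 / 2) / 5, tolerance = 1e-12)
  expect_equal(critical_mu_tot(0.5, 5), 1.187, tolerance = 1e-3)
  a <- seq(0, 3, by = 0.25)
  expect_true(all(diff(critical_mu_tot(a, 5)) > 0))
})

test_that("the fastest admissible mode is q = pi except far above threshold", {
  q <- fastest_mode(0.5, 5, 2)
  expect_equal(as.numeric(q), pi)
  expect_false(attr(q, "above_pi"))
  # just above threshold only q = pi is unstable
  q2 <- fastest_mode(1, 5, critical_mu_tot(1, 5) * 1.05)
  expect_equal(as.numeric(q2), pi)
  lam2 <- dispersion_rate(pi * (1:8), 1, 5, critical_mu_tot(1, 5) * 1.05)
  expect_true(all(lam2[-1] < 0))
  # far above threshold the arg-max can leave q = pi (flagged regime)
  q3 <- fastest_mode(0.01, 5, 10)
  expect_gt(as.numeric(q3), pi)
  expect_true(attr(q3, "above_pi"))
  # brute-force scan of the analytic rate agrees
  qs <- pi * (1:32)
  expect_equal(as.numeric(q3), qs[which.max(dispersion_rate(qs, 0.01, 5, 10))])
})

test_that("1D simulation reproduces the analytic growth and decay rates", {
  # growth above threshold, fitted within 5%
  lam <- dispersion_rate(pi, 0.5, 5, 2)
  r <- simulate_1d_zv(0.5, 5, 2, n = 400, dt = 5e-4, t_end = 0.4,
                      amplitude = 1e-5)
  fit <- fit_growth_rate(r$times, r$mode_amplitude, t_min = 0.05, t_max = 0.35)
  expect_equal(fit, lam, tolerance = 0.05)
  # decay below threshold
  mu_lo <- 0.8 * critical_mu_tot(0.5, 5)
  r2 <- simulate_1d_zv(0.5, 5, mu_lo, n = 300, dt = 1e-3, t_end = 0.5,
                       amplitude = 1e-4)
  lam_lo <- dispersion_rate(pi, 0.5, 5, mu_lo)
  expect_lt(lam_lo, 0)
  fit2 <- fit_growth_rate(r2$times, r2$mode_amplitude, t_min = 0.05,
                          t_max = 0.45)
  expect_equal(fit2, lam_lo, tolerance = 0.1)
})

test_that("the uniform unperturbed state is an exact 1D steady state", {
  r <- simulate_1d_zv(0.5, 5, 2, n = 100, dt = 0.01, t_end = 0.2,
                      amplitude = 0)
  expect_lt(max(abs(r$m[nrow(r$m), ] - 2)), 1e-12)
  expect_lt(max(abs(r$u)), 1e-12)
})

test_that("1D transport conserves mass and positivity", {
  r <- simulate_1d_zv(0.5, 5, 3, n = 200, dt = 1e-3, t_end = 1,
                      amplitude = 1e-3)
  dx <- 1 / 200
  masses <- rowSums(r$m) * dx
  expect_lt(max(abs(masses - 3)), 1e-11)
  expect_true(all(r$m >= 0))
})

test_that("rescaling (beta, mu_tot) -> (beta/c, c mu_tot) preserves beta*m", {
  r1 <- simulate_1d_zv(0.5, 5, 2, n = 200, dt = 1e-3, t_end = 0.3,
                       amplitude = 1e-4)
  r2 <- simulate_1d_zv(0.5, 2.5, 4, n = 200, dt = 1e-3, t_end = 0.3,
                       amplitude = 1e-4)
  expect_equal(5 * r1$m[nrow(r1$m), ], 2.5 * r2$m[nrow(r2$m), ],
               tolerance = 1e-12)
})
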