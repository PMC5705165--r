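#' Dispersion relation of the 1D ZV model
#'
#' Growth rate of a sinusoidal perturbation of wavenumber `q` about the
#' uniform stationary state (`u = 0`, `m = mu_tot`) of the one-dimensional
#' zero-velocity model on the unit segment with crowding cutoffs disabled:
#' \deqn{\lambda(q) = q^2\left(\frac{\beta\mu_{tot}}{1 + \alpha q^2} - 1\right).}
#' Admissible wavenumbers are \eqn{q = \pi, 2\pi, \ldots} (no-flux /
#' zero-velocity boundary conditions). The state is unstable when
#' \eqn{\beta\mu_{tot} > 1 + \pi^2\alpha}.
#'
#' @param q Wavenumber (vectorized, positive).
#' @param alpha Viscosity-adhesion length parameter.
#' @param beta Contractility constant.
#' @param mu_tot Total dimensionless myosin.
#' @return Growth rate(s) `lambda`.
#' @export
#' @examples
#' dispersion_rate(pi, 0.5, 5, 2)
dispersion_rate <- function(q, alpha, beta, mu_tot) {
  if (any(q <= 0)) stop("'q' must be positive", call. = FALSE)
  if (alpha <= 0) stop("'alpha' must be positive", call. = FALSE)
  if (beta * mu_tot < 0) stop("'beta * mu_tot' must be >= 0", call. = FALSE)
  q^2 * (beta * mu_tot / (1 + alpha * q^2) - 1)
}

#' Critical total myosin for motility initiation
#'
#' The uniform state loses stability when \eqn{\beta\mu_{tot} > 1 + \pi^2\alpha},
#' so the critical myosin load is \eqn{(1 + \pi^2\alpha)/\beta}; it increases
#' with the viscosity-adhesion length `alpha`.
#'
#' @param alpha Viscosity-adhesion length parameter (`>= 0`).
#' @param beta Contractility constant (`> 0`).
#' @return Critical `mu_tot`.
#' @export
critical_mu_tot <- function(alpha, beta) {
  if (any(alpha < 0)) stop("'alpha' must be >= 0", call. = FALSE)
  if (any(beta <= 0)) stop("'beta' must be positive", call. = FALSE)
  (1 + pi^2 * alpha) / beta
}

#' Fastest growing admissible mode
#'
#' Arg-max of [dispersion_rate()] over the admissible wavenumbers
#' `q = pi, 2*pi, ..., q_max_index*pi`. Just above threshold only `q = pi` is
#' unstable, and for the model's monotone dispersion branch the minimal
#' wavenumber is the fastest; very large `beta*mu_tot` can formally shift the
#' arg-max upward, which is flagged via the `above_pi` attribute.
#'
#' @inheritParams dispersion_rate
#' @param q_max_index Number of admissible modes scanned.
#' @return The fastest wavenumber, with attributes `lambda` and `above_pi`.
#' @export
fastest_mode <- function(alpha, beta, mu_tot, q_max_index = 32) {
  qs <- pi * seq_len(q_max_index)
  lam <- dispersion_rate(qs, alpha, beta, mu_tot)
  i <- which.max(lam)
  structure(qs[i], lambda = lam[i], above_pi = i > 1L)
}

#' Simulate the 1D ZV model on the unit segment
#'
#' Finite-volume solve of \eqn{\alpha u_{xx} + \beta m_x - u = 0},
#' \eqn{m_t = m_{xx} - (u m)_x} on \eqn{x \in (0, 1)} with `u(0) = u(1) = 0`
#' and no myosin flux through the ends (crowding cutoffs disabled, matching
#' the reduction used for the stability analysis). The initial condition is
#' the uniform state plus a small cosine perturbation of wavenumber `q`;
#' the returned amplitude series is the projection of `m - mu_tot` onto
#' `cos(q x)` and should grow or decay at the analytic rate
#' [dispersion_rate()] while the dynamics stay linear.
#'
#' @param alpha,beta,mu_tot Model parameters.
#' @param n Number of grid cells.
#' @param dt Time step (backward Euler).
#' @param t_end Final time.
#' @param amplitude Relative perturbation amplitude (keep `<= 1e-3` for
#'   linear-regime comparisons).
#' @param q Perturbation wavenumber (`pi, 2*pi, ...`).
#' @return List with `x`, `times`, `m` (matrix, rows = times), `u`, and
#'   `mode_amplitude`.
#' @export
simulate_1d_zv <- function(alpha, beta, mu_tot, n = 200, dt = 1e-3,
                           t_end = 1, amplitude = 1e-4, q = pi) {
  dx <- 1 / n
  x <- (seq_len(n) - 0.5) * dx
  m <- mu_tot * (1 + amplitude * cos(q * x))
  nt <- ceiling(t_end / dt)
  times <- numeric(nt + 1L)
  amps <- numeric(nt + 1L)
  msnap <- matrix(NA_real_, nt + 1L, n)
  proj <- function(m) 2 * sum((m - mu_tot) * cos(q * x)) * dx
  amps[1L] <- proj(m)
  msnap[1L, ] <- m
  # u operator: alpha*u'' - u with u = 0 at segment ends (ghost closure)
  main_u <- rep(-2 * alpha / dx^2 - 1, n)
  main_u[c(1L, n)] <- -3 * alpha / dx^2 - 1
  off_u <- rep(alpha / dx^2, n - 1L)
  u_of_m <- function(m) {
    mx <- numeric(n)
    mx[2:(n - 1)] <- (m[3:n] - m[1:(n - 2)]) / (2 * dx)
    mx[1L] <- (m[2L] - m[1L]) / dx
    mx[n] <- (m[n] - m[n - 1L]) / dx
    tri_solve(main_u, off_u, off_u, -beta * mx)
  }
  u <- u_of_m(m)
  for (s in seq_len(nt)) {
    u <- u_of_m(m)
    uf <- c(0, 0.5 * (u[-n] + u[-1L]), 0) # face velocities, zero at ends
    # implicit FV: (vol/dt + D + A) m_new = vol/dt m_old
    lo <- numeric(n - 1L); di <- numeric(n); up <- numeric(n - 1L)
    di[] <- dx / dt
    for (i in seq_len(n - 1L)) { # face between i and i+1
      d <- 1 / dx
      di[i] <- di[i] + d; up[i] <- up[i] - d
      di[i + 1L] <- di[i + 1L] + d; lo[i] <- lo[i] - d
      un <- uf[i + 1L]
      if (un > 0) {
        di[i] <- di[i] + un
        lo[i] <- lo[i] - un
      } else {
        up[i] <- up[i] + un
        di[i + 1L] <- di[i + 1L] - un
      }
    }
    m <- tri_solve(di, lo, up, dx / dt * m)
    if (max(abs(m)) > 1e6) {
      stop("1D solution blew up: nonlinear regime reached", call. = FALSE)
    }
    times[s + 1L] <- s * dt
    amps[s + 1L] <- proj(m)
    msnap[s + 1L, ] <- m
  }
  list(x = x, times = times, m = msnap, u = u, mode_amplitude = amps)
}

# dense tridiagonal solve (Thomas algorithm)
tri_solve <- function(diag, lower, upper, rhs) {
  n <- length(diag)
  cp <- numeric(n); dp <- numeric(n)
  cp[1L] <- upper[1L] / diag[1L]
  dp[1L] <- rhs[1L] / diag[1L]
  for (i in 2:n) {
    denom <- diag[i] - lower[i - 1L] * cp[i - 1L]
    if (i < n) cp[i] <- upper[i] / denom
    dp[i] <- (rhs[i] - lower[i - 1L] * dp[i - 1L]) / denom
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1L):1L) x[i] <- dp[i] - cp[i] * x[i + 1L]
  x
}

#' Fit an exponential growth rate to a mode-amplitude series
#'
#' Log-linear least squares on `|amplitude|` over the given time window.
#' @param times,amps Series from [simulate_1d_zv()].
#' @param t_min,t_max Fit window.
#' @return The fitted rate (slope of `log|a|`).
#' @export
fit_growth_rate <- function(times, amps, t_min = 0, t_max = Inf) {
  sel <- times >= t_min & times <= t_max & abs(amps) > 0
  stats::coef(stats::lm(log(abs(amps[sel])) ~ times[sel]))[[2L]]
}
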