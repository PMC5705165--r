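#' Solver settings
#'
#' Numerical parameters of the free-boundary simulation. The time step is
#' `dt = c * h`, additionally capped so that the boundary moves at most
#' `cfl` cells per step.
#'
#' @param h Mesh spacing, in `[0.01, 0.5]`.
#' @param c Time-step factor, `dt = c * h`.
#' @param fp_tol Fixed-point tolerance on the maximum absolute difference of
#'   consecutive iterates (both velocity and myosin).
#' @param max_iters Cap on fixed-point iterations per time step.
#' @param t_end Final dimensionless time.
#' @param snapshot_stride Keep a full field snapshot every this many steps
#'   (0 = none).
#' @param n_markers Initial marker count on the unit circle.
#' @param merge_thresh Cut-cell merge threshold (see [build_mesh()]).
#' @param cfl Maximum boundary displacement per step in units of `h`.
#' @param d_floor Effective-diffusivity floor.
#' @param boundary_filter Number of binomial smoothing passes applied to
#'   per-marker extrapolated boundary values (removes grid-frequency stencil
#'   jitter; 0 disables).
#' @return An object of class `"solver_settings"`.
#' @export
solver_settings <- function(h = 0.16, c = 0.01, fp_tol = 1e-10,
                            max_iters = 35, t_end = 30, snapshot_stride = 0,
                            n_markers = 256, merge_thresh = 0.3, cfl = 0.9,
                            d_floor = 1e-6, boundary_filter = 2L) {
  if (h < 0.01 || h > 0.5) stop("'h' must lie in [0.01, 0.5]", call. = FALSE)
  if (c <= 0) stop("'c' must be positive", call. = FALSE)
  if (fp_tol <= 0) stop("'fp_tol' must be positive", call. = FALSE)
  if (max_iters < 1) stop("'max_iters' must be >= 1", call. = FALSE)
  structure(list(h = h, c = c, fp_tol = fp_tol, max_iters = max_iters,
                 t_end = t_end, snapshot_stride = snapshot_stride,
                 n_markers = n_markers, merge_thresh = merge_thresh,
                 cfl = cfl, d_floor = d_floor,
                 boundary_filter = as.integer(boundary_filter)),
            class = "solver_settings")
}

#' Initial simulation state
#'
#' The standard initial condition: the unit circle (area \eqn{\pi}), zero
#' actin velocity, and a linear horizontal myosin gradient superimposed on the
#' uniform distribution, \eqn{m(x, 0) = (\mu_{tot}/|\omega|)(1 - g x)}. The
#' gradient probes the stability of the radially symmetric state; since `x`
#' is odd over the disk the prescribed total myosin is unchanged, and the
#' discrete field is rescaled so that the total equals `mu_tot` exactly.
#'
#' @param p A [motility_params()] object.
#' @param settings A [solver_settings()] object.
#' @return An object of class `"simulation_state"`: fields `t`, `curve`,
#'   `mesh`, `m`, `u` (G x 2), and a `diagnostics` row (area, centroid, total
#'   myosin, iterations, max m).
#' @export
initial_condition <- function(p, settings = solver_settings()) {
  curve <- circle_curve(1, c(0, 0), settings$n_markers)
  mesh <- build_mesh(curve, settings$h, settings$merge_thresh)
  a <- mesh$area
  m <- (p$mu_tot / a) * (1 - p$g * mesh$gcx)
  m <- pmax(m, 0)
  m <- m * p$mu_tot / sum(m * mesh$gvol)
  state <- list(t = 0, curve = curve, mesh = mesh, m = m,
                u = matrix(0, mesh$G, 2), fp_iters = NA_integer_,
                max_vf = NA_real_, floor_hits = 0L)
  class(state) <- "simulation_state"
  state
}

#' @export
print.simulation_state <- function(x, ...) {
  cc <- curve_centroid(x$curve)
  cat(sprintf(
    "<simulation_state> t = %.4f, area = %.4f, centroid = (%.4f, %.4f), total myosin = %.6f\n",
    x$t, enclosed_area(x$curve), cc[1], cc[2], total_mass(x$mesh, x$m)))
  invisible(x)
}

# binomial smoothing of per-marker boundary values: the bilinear
# extrapolation stencil switches discretely as markers move past cell
# boundaries, which leaves grid-frequency jitter on the extrapolated trace;
# a short periodic binomial filter removes it without affecting resolved
# scales (the filter width is far below the instability wavelengths)
smooth_periodic <- function(v, passes = 2L) {
  if (passes <= 0L) return(v)
  n <- length(v)
  for (k in seq_len(passes)) {
    v <- 0.25 * v[c(n, 1:(n - 1L))] + 0.5 * v + 0.25 * v[c(2:n, 1L)]
  }
  v
}

# boundary kinematics shared by segregated and monolithic steps:
# compute v_p/u_b, advance the front, rebuild the mesh, transfer mass
advance_state <- function(state, m_new, u_new, dt, settings, p) {
  curve <- state$curve
  mesh <- state$mesh
  a <- enclosed_area(curve)
  nm <- outward_normals(curve, verify = FALSE)
  np <- settings$boundary_filter
  if (p$variant == "ZV") {
    mb <- extrapolate_to_boundary(mesh, m_new, curve$markers, nm)
    mb <- smooth_periodic(as.numeric(mb), np)
    v_p <- protrusion_rate_zv(a, pmax(mb, 0), p)
    u_b <- NULL
  } else {
    v_p <- protrusion_rate_zs(a, p)
    ubx <- smooth_periodic(as.numeric(
      extrapolate_to_boundary(mesh, u_new[, 1], curve$markers, nm)), np)
    uby <- smooth_periodic(as.numeric(
      extrapolate_to_boundary(mesh, u_new[, 2], curve$markers, nm)), np)
    u_b <- cbind(ubx, uby)
  }
  bv <- assemble_boundary_velocity(curve, v_p, u_b, p$variant)
  curve_new <- advance_front(curve, bv, dt)
  mesh_new <- build_mesh(curve_new, settings$h, settings$merge_thresh)
  tr <- transfer_mass(m_new, mesh, mesh_new)
  u_guess <- transfer_field_cpp(mesh, mesh_new, u_new)
  state_new <- list(
    t = state$t + dt, curve = curve_new, mesh = mesh_new, m = tr$m,
    u = u_guess, fp_iters = state$fp_iters,
    max_vf = max(sqrt(rowSums(bv$v_f^2))), floor_hits = state$floor_hits)
  class(state_new) <- "simulation_state"
  state_new
}

step_dt <- function(state, settings) {
  dt <- settings$c * settings$h
  if (is.finite(state$max_vf) && state$max_vf > 0) {
    dt <- min(dt, settings$cfl * settings$h / state$max_vf)
  }
  dt
}

#' One segregated time step
#'
#' Advances the state by one time step of the segregated fixed-point scheme:
#' within the step the mesh is held fixed and the loop alternates (1) a
#' force-balance solve using the previous iterate's myosin, (2) evaluation of
#' the crowding-limited coefficients from that myosin and the new velocity,
#' and (3) one backward-Euler transport solve anchored at the previous time
#' step's myosin, until the maximum absolute differences of consecutive
#' iterates fall below `fp_tol`. After convergence the protrusion rate is
#' evaluated, the boundary velocity assembled, the front advanced, the mesh
#' rebuilt and the myosin mass transferred conservatively.
#'
#' @param state A [initial_condition()] state (or a previous step's output).
#' @param settings A [solver_settings()] object.
#' @param p A [motility_params()] object.
#' @param dt Optional time step override (defaults to `c*h`, CFL-capped).
#' @return The advanced `"simulation_state"`; `$fp_iters` records the
#'   iterations used.
#' @export
segregated_step <- function(state, settings, p, dt = NULL) {
  if (is.null(dt)) dt <- step_dt(state, settings)
  mesh <- state$mesh
  anchor <- state$m * mesh$gvol
  r <- segregated_solve_cpp(mesh, anchor, state$m, state$u, dt,
                            p$alpha, p$beta, p$mmax_u, p$mmax_d,
                            variant_code(p$variant), settings$fp_tol,
                            settings$max_iters, settings$d_floor)
  if (!r$converged) {
    stop(sprintf(
      "iterations are stagnant: %d iterations, err_u = %.3e, err_m = %.3e",
      r$iters, r$err_u, r$err_m), call. = FALSE)
  }
  state$fp_iters <- r$iters
  state$floor_hits <- state$floor_hits + r$floor_hits
  advance_state(state, r$m, r$u, dt, settings, p)
}

#' One fully coupled reference step
#'
#' Solves the same one-step system as [segregated_step()] but to full
#' self-consistency: the fixed-point iteration is driven to a tolerance of
#' `1e-13` (cap 500 iterations) and the residuals of the coupled nonlinear
#' system at the returned iterate are verified below `res_tol`. Used to
#' validate the production segregated solver; the boundary kinematics are
#' identical.
#'
#' @inheritParams segregated_step
#' @param res_tol Acceptance threshold for the coupled residuals.
#' @return The advanced `"simulation_state"`.
#' @export
monolithic_step <- function(state, settings, p, dt = NULL, res_tol = 1e-9) {
  if (is.null(dt)) dt <- step_dt(state, settings)
  mesh <- state$mesh
  anchor <- state$m * mesh$gvol
  r <- segregated_solve_cpp(mesh, anchor, state$m, state$u, dt,
                            p$alpha, p$beta, p$mmax_u, p$mmax_d,
                            variant_code(p$variant), 1e-13, 500L,
                            settings$d_floor)
  if (!r$converged) {
    stop("coupled reference solve did not converge", call. = FALSE)
  }
  res <- coupled_residual_cpp(mesh, anchor, r$m, r$u, dt, p$alpha, p$beta,
                              p$mmax_u, p$mmax_d, variant_code(p$variant),
                              settings$d_floor)
  scale <- max(1, max(abs(r$m)) * max(mesh$gvol))
  if (max(res$res_u, res$res_m) > res_tol * scale) {
    stop(sprintf("coupled reference solve residuals too large (%.3e, %.3e)",
                 res$res_u, res$res_m), call. = FALSE)
  }
  state$fp_iters <- r$iters
  advance_state(state, r$m, r$u, dt, settings, p)
}

#' Run a full free-boundary simulation
#'
#' Steps the coupled system from the standard initial condition to `t_end`,
#' recording per-step diagnostics. The pipeline is fully deterministic: no
#' random numbers are used anywhere.
#'
#' @param p A [motility_params()] object.
#' @param settings A [solver_settings()] object.
#' @param stop_when_steady Stop early once the steadiness criterion (speed and
#'   aspect ratio within 2\% of their trailing 5-time-unit means) has held for
#'   `steady_margin` additional time units.
#' @param steady_margin Extra time to integrate beyond detected steadiness.
#' @param stepper Step function, [segregated_step()] by default.
#' @return An object of class `"cell_simulation"`: `params`, `settings`,
#'   `diagnostics` (a tibble with one row per step: `t`, centroid `x`/`y`,
#'   `area`, `speed`, `aspect_ratio`, `total_myosin`, `fp_iters`, `max_m`),
#'   the final `state`, and optional field `snapshots`.
#' @export
run_simulation <- function(p, settings = solver_settings(),
                           stop_when_steady = FALSE, steady_margin = 2,
                           stepper = segregated_step) {
  state <- initial_condition(p, settings)
  n_guess <- ceiling(settings$t_end / (settings$c * settings$h)) + 2L
  diag <- matrix(NA_real_, n_guess, 9L)
  colnames(diag) <- c("t", "x", "y", "area", "speed", "aspect_ratio",
                      "total_myosin", "fp_iters", "max_m")
  snapshots <- list()
  record <- function(k, state, speed) {
    cc <- curve_centroid(state$curve)
    diag[k, ] <<- c(state$t, cc[1], cc[2], enclosed_area(state$curve), speed,
                    aspect_ratio(state$curve), total_mass(state$mesh, state$m),
                    as.numeric(state$fp_iters), max(state$m))
  }
  record(1L, state, NA_real_)
  if (settings$snapshot_stride > 0) snapshots[[1L]] <- state
  k <- 1L
  next_check <- 5
  speed_lag <- 0.25 # time base for the centroid speed (suppresses the
                    # remeshing jitter a one-step difference would amplify)
  while (state$t < settings$t_end - 1e-12) {
    state <- stepper(state, settings, p)
    k <- k + 1L
    if (k > nrow(diag)) diag <- rbind(diag, matrix(NA_real_, 1024L, 9L))
    cc <- curve_centroid(state$curve)
    jlag <- findInterval(state$t - speed_lag, diag[seq_len(k - 1L), 1L])
    jlag <- max(1L, min(jlag, k - 1L))
    dtk <- state$t - diag[jlag, 1L]
    speed <- sqrt((cc[1] - diag[jlag, 2L])^2 +
                  (cc[2] - diag[jlag, 3L])^2) / dtk
    record(k, state, speed)
    if (settings$snapshot_stride > 0 &&
        (k - 1L) %% settings$snapshot_stride == 0L) {
      snapshots[[length(snapshots) + 1L]] <- state
    }
    if (stop_when_steady && state$t >= next_check) {
      next_check <- state$t + 1
      rec <- diagnostics_tibble(diag[seq_len(k), , drop = FALSE])
      st <- detect_steady(rec)
      if (is.finite(st) && state$t >= st + 5 + steady_margin) break
    }
  }
  out <- list(params = p, settings = settings,
              diagnostics = diagnostics_tibble(diag[seq_len(k), , drop = FALSE]),
              state = state, snapshots = snapshots)
  class(out) <- "cell_simulation"
  out
}

diagnostics_tibble <- function(m) {
  tibble::as_tibble(as.data.frame(m))
}

#' @export
print.cell_simulation <- function(x, ...) {
  d <- x$diagnostics
  n <- nrow(d)
  cat(sprintf("<cell_simulation> %s model, %d steps to t = %.3f\n",
              x$params$variant, n - 1L, d$t[n]))
  cat(sprintf("  final area %.4f, aspect ratio %.3f, speed %.4f, total myosin %.6f\n",
              d$area[n], d$aspect_ratio[n], d$speed[n], d$total_myosin[n]))
  invisible(x)
}
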