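#' Load a run configuration from YAML
#'
#' Reads a YAML file with optional sections `model`, `solver` and `output`,
#' fills every missing field with the package default (the fixed parameter
#' values \eqn{\beta = 5}, \eqn{k = 1.5}, \eqn{a_0 = \pi},
#' \eqn{m_{max,u} = 15}, \eqn{m_{max,d} = 125} among them) and validates the
#' result. Unknown keys are rejected with an error naming the key.
#'
#' @param path Path to a YAML file. The file must at least name the model
#'   `variant`.
#' @return A list of class `"run_config"` with elements `model`
#'   ([motility_params()]), `solver` ([solver_settings()]) and `output`
#'   (list with `directory`, `stride`, `write_vtk`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  as_run_config(raw)
}

#' Build a validated run configuration from a list
#'
#' @param raw Nested list as produced by parsing the YAML config.
#' @return See [load_config()].
#' @export
as_run_config <- function(raw) {
  known_top <- c("model", "solver", "output")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown) > 0) {
    stop("unknown configuration section: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  model <- raw$model
  if (is.null(model)) model <- list()
  if (is.null(model$variant)) {
    stop("configuration must name the model variant (ZS or ZV)",
         call. = FALSE)
  }
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad) > 0) {
      stop("unknown key in ", where, ": ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  check_keys(model, names(formals(motility_params)), "model")
  pm <- do.call(motility_params, model)
  solver <- raw$solver
  if (is.null(solver)) solver <- list()
  check_keys(solver, names(formals(solver_settings)), "solver")
  ss <- do.call(solver_settings, solver)
  output <- raw$output
  if (is.null(output)) output <- list()
  check_keys(output, c("directory", "stride", "write_vtk"), "output")
  out <- list(directory = output$directory %||% ".",
              stride = output$stride %||% 0L,
              write_vtk = isTRUE(output$write_vtk))
  structure(list(model = pm, solver = ss, output = out),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_as_list <- function(cfg) {
  pm <- unclass(cfg$model)
  pm$n_exp <- NULL
  list(model = pm, solver = unclass(cfg$solver), output = cfg$output)
}

#' Write simulation outputs to a directory
#'
#' Writes `diagnostics.csv` (one row per step), `boundary.csv` (marker
#' positions of the stored snapshots, columns `t`, `marker`, `x`, `y`),
#' optional VTK legacy field snapshots, and `manifest.yaml` (the full
#' configuration and resolved numerical knobs, sufficient to regenerate every
#' file with [run_from_manifest()]).
#'
#' @param sim A [run_simulation()] result.
#' @param directory Output directory (created if missing).
#' @param write_vtk Also write field snapshots in VTK legacy format.
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(sim, directory, write_vtk = FALSE) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  pd <- file.path(directory, "diagnostics.csv")
  utils::write.csv(sim$diagnostics, pd, row.names = FALSE)
  paths <- c(paths, pd)
  snaps <- sim$snapshots
  if (length(snaps) == 0) snaps <- list(sim$state)
  bnd <- do.call(rbind, lapply(snaps, function(s) {
    mk <- s$curve$markers
    data.frame(t = s$t, marker = seq_len(nrow(mk)), x = mk[, 1], y = mk[, 2])
  }))
  pb <- file.path(directory, "boundary.csv")
  utils::write.csv(bnd, pb, row.names = FALSE)
  paths <- c(paths, pb)
  if (write_vtk) {
    for (i in seq_along(snaps)) {
      pv <- file.path(directory, sprintf("fields_%04d.vtk", i))
      write_vtk_fields(snaps[[i]], pv)
      paths <- c(paths, pv)
    }
  }
  cfg <- list(model = unclass(sim$params), solver = unclass(sim$settings))
  cfg$model$n_exp <- NULL
  pmf <- file.path(directory, "manifest.yaml")
  # full double precision so a manifest re-run reproduces the run bitwise
  yaml::write_yaml(list(actomotion_run = cfg), pmf, precision = 17)
  paths <- c(paths, pmf)
  invisible(paths)
}

#' Re-run a simulation from its manifest
#'
#' The manifest records every parameter and numerical knob; because the
#' pipeline is deterministic, re-running reproduces the original diagnostics
#' bitwise.
#'
#' @param path Path to a `manifest.yaml` written by [write_outputs()].
#' @param ... Passed on to [run_simulation()].
#' @return A [run_simulation()] result.
#' @export
run_from_manifest <- function(path, ...) {
  mf <- yaml::read_yaml(path)$actomotion_run
  p <- do.call(motility_params, mf$model)
  s <- do.call(solver_settings, mf$solver)
  run_simulation(p, s, ...)
}

# legacy-VTK structured-points snapshot: myosin, velocity and volume fraction
# on the background window (exterior cells carry volume fraction 0)
write_vtk_fields <- function(state, path) {
  mesh <- state$mesh
  nx <- mesh$nx; ny <- mesh$ny
  grp <- mesh$grp
  val <- function(field, default = 0) {
    v <- matrix(default, nx, ny)
    act <- grp > 0
    v[act] <- field[grp[act]]
    v
  }
  mm <- val(state$m)
  ux <- val(state$u[, 1]); uy <- val(state$u[, 2])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("actomotion fields t=%.8f", state$t),
               "ASCII", "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", nx, ny),
               sprintf("ORIGIN %.10g %.10g 0",
                       (mesh$ix0 + 0.5) * mesh$h, (mesh$iy0 + 0.5) * mesh$h),
               sprintf("SPACING %.10g %.10g 1", mesh$h, mesh$h),
               sprintf("POINT_DATA %d", nx * ny)), con)
  wr <- function(name, v) {
    writeLines(c(sprintf("SCALARS %s double 1", name), "LOOKUP_TABLE default"),
               con)
    writeLines(paste(format(as.vector(v), digits = 10), collapse = " "), con)
  }
  wr("myosin", mm)
  wr("volume_fraction", mesh$f)
  writeLines("VECTORS velocity double", con)
  vec <- rbind(as.vector(ux), as.vector(uy), 0)
  writeLines(paste(format(as.vector(vec), digits = 10), collapse = " "), con)
  invisible(path)
}

#' Manufactured-solution convergence benchmark
#'
#' Verifies the spatial order of the transport discretization in the
#' diffusion-dominated regime (advection off), where second order is the
#' contract. The exact solution on the fixed unit disk,
#' \deqn{m^*(r, t) = e^{-t}\,(r^4/4 - r^2/2 + 1),}
#' satisfies the no-flux condition at the rim (\eqn{\partial_r m^* = 0} at
#' `r = 1`); the matching source term is applied and the backward-Euler step
#' is scaled as `dt = dt_factor * h^2` so the temporal error refines with the
#' spatial one.
#'
#' @param levels Mesh spacings (finest last), at least 3 for orders.
#' @param t_end Final time.
#' @param dt_factor Time-step factor in `dt = dt_factor * h^2`.
#' @param n_markers Markers on the unit circle per level (scaled with `1/h`).
#' @return A tibble with columns `h`, `n`, `l2_error` and `order`
#'   (pairwise observed order, `NA` for the first level).
#' @export
manufactured_benchmark <- function(levels = c(0.16, 0.08, 0.04),
                                   t_end = 0.25, dt_factor = 0.2,
                                   n_markers = NULL) {
  if (length(levels) < 2) stop("need at least 2 levels", call. = FALSE)
  exact <- function(r, t) exp(-t) * (r^4 / 4 - r^2 / 2 + 1)
  src <- function(r) -(r^4 / 4 + 3.5 * r^2 - 1)
  rows <- lapply(levels, function(h) {
    nmk <- if (is.null(n_markers)) max(256L, 2L^ceiling(log2(8 * pi / h)))
           else n_markers
    curve <- circle_curve(1, c(0, 0), nmk)
    mesh <- build_mesh(curve, h)
    r <- sqrt(mesh$gcx^2 + mesh$gcy^2)
    dt <- dt_factor * h^2
    nsteps <- ceiling(t_end / dt)
    dt <- t_end / nsteps
    m0 <- exact(r, 0)
    mT <- bench_diffusion_cpp(mesh, m0, src(r), 1, dt, nsteps)
    err <- sqrt(sum(mesh$gvol * (mT - exact(r, t_end))^2))
    tibble::tibble(h = h, n = mesh$G, l2_error = err)
  })
  out <- do.call(rbind, rows)
  out$order <- c(NA, log(out$l2_error[-nrow(out)] / out$l2_error[-1]) /
                   log(out$h[-nrow(out)] / out$h[-1]))
  if (any(diff(out$l2_error) > 0)) {
    warning("benchmark error decay is not monotone", call. = FALSE)
  }
  out
}
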