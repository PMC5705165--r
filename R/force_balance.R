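#' Solve the actin force balance on a mesh
#'
#' Solves the dimensionless elliptic force balance
#' \eqn{\alpha \Delta u + \beta \nabla m - u = 0} for the actin velocity field
#' given the myosin density, under the variant's boundary condition:
#' \itemize{
#' \item ZV: \eqn{u = 0} on the boundary, imposed through one-sided fluxes at
#'   the cut cells;
#' \item ZS: \eqn{n \cdot (\alpha \nabla u + \beta m \hat I) = 0}, imposed
#'   weakly -- the viscous and contractile boundary-segment contributions to
#'   the finite-volume balance cancel exactly, so cut cells simply carry no
#'   front flux.
#' }
#' The two velocity components decouple (the viscous term is the componentwise
#' Laplacian) and share one factorized operator; the myosin gradient enters
#' through face-averaged values and, for ZV, the extrapolated boundary myosin.
#'
#' @param mesh A [build_mesh()] result.
#' @param m Myosin density per mesh unknown.
#' @param p A [motility_params()] object (uses `alpha`, `beta`, `variant`).
#' @return List of class `"velocity_field"` with `ux`, `uy` (per unknown) and
#'   the linear-system residual `residual` (max norm).
#' @export
solve_force_balance <- function(mesh, m, p) {
  if (length(m) != mesh$G) {
    stop("'m' must have one entry per mesh unknown", call. = FALSE)
  }
  if (any(m < -1e-12)) stop("myosin density must be non-negative", call. = FALSE)
  r <- fb_solve_cpp(mesh, as.numeric(m), p$alpha, p$beta,
                    variant_code(p$variant))
  if (!all(is.finite(r$ux)) || !all(is.finite(r$uy))) {
    stop("force-balance solve produced non-finite velocities", call. = FALSE)
  }
  structure(list(ux = r$ux, uy = r$uy, residual = r$residual,
                 residual_pointwise = r$residual_pointwise),
            class = "velocity_field")
}

#' One implicit transport step for myosin
#'
#' Advances the myosin density by one backward-Euler step of the conservative
#' advection--diffusion equation
#' \eqn{\partial_t m = \nabla\cdot(d_{eff}\nabla m - u_{eff} m)}
#' with crowding-limited coefficients and zero flux through the cell edge.
#' Diffusive face fluxes are two-point, advective fluxes first-order upwind on
#' the effective velocity, and boundary-segment fluxes are identically zero,
#' which enforces the no-flux Rankine--Hugoniot condition by construction: the
#' sweeping effect of the moving boundary is realized geometrically by the
#' conservative [transfer_mass()] between the old and new meshes.
#'
#' @param mesh_prev Mesh carrying `m_prev`.
#' @param mesh_next Mesh after the boundary moved (may equal `mesh_prev`).
#' @param m_prev Myosin density per `mesh_prev` unknown (the backward-Euler
#'   anchor).
#' @param u Actin velocity per `mesh_next` unknown (`G x 2` matrix or a
#'   `velocity_field`).
#' @param dt Positive time step.
#' @param p A [motility_params()] object.
#' @param m_coef Density used to evaluate the crowding-limited coefficients
#'   (defaults to the transferred `m_prev`, i.e. a lagged linearization).
#' @param d_floor Diffusivity floor (see [effective_diffusivity()]).
#' @return List with `m` (density per `mesh_next` unknown), `mass`, and
#'   `floor_hits` (number of cells where the diffusivity floor fired).
#' @export
transport_step <- function(mesh_prev, mesh_next, m_prev, u, dt, p,
                           m_coef = NULL, d_floor = 1e-6) {
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be positive", call. = FALSE)
  tr <- transfer_mass(m_prev, mesh_prev, mesh_next)
  if (inherits(u, "velocity_field")) u <- cbind(u$ux, u$uy)
  u <- as.matrix(u)
  if (nrow(u) != mesh_next$G) {
    stop("'u' must align with the unknowns of 'mesh_next'", call. = FALSE)
  }
  if (is.null(m_coef)) m_coef <- tr$m
  r <- transport_step_cpp(mesh_next, tr$mass, as.numeric(m_coef), u, dt,
                          p$mmax_u, p$mmax_d, d_floor, numeric(0))
  m <- r$m
  if (min(m) < -1e-12) {
    stop("transport step lost positivity (min m = ", format(min(m)), ")",
         call. = FALSE)
  }
  if (r$floor_hits > 0) {
    warning("effective diffusivity floored in ", r$floor_hits,
            " cell(s); myosin density exceeded mmax_d", call. = FALSE)
  }
  list(m = m, mass = m * mesh_next$gvol, floor_hits = r$floor_hits)
}
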