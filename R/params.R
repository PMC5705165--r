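#' Dimensionless model parameters
#'
#' Bundles the governing constants of the free-boundary actomyosin model in
#' dimensionless form. The model couples an elliptic force balance for the
#' actin flow `u`, \eqn{\alpha \Delta u + \beta \nabla m - u = 0}, to a
#' conservative advection--diffusion equation for the myosin density `m` on a
#' moving domain. Two variants differ in the boundary condition for the force
#' balance: `"ZV"` imposes zero actin velocity at the cell edge, `"ZS"` a zero
#' total (viscous + contractile) stress.
#'
#' @param variant `"ZV"` (zero velocity) or `"ZS"` (zero stress).
#' @param alpha Viscosity-adhesion length parameter \eqn{\alpha = \eta/(L^2\xi)}:
#'   the squared ratio of the mechanical interaction length \eqn{\sqrt{\eta/\xi}}
#'   to the cell radius.
#' @param beta Myosin contractility constant \eqn{\beta = \sigma M_0/(D\xi)}.
#' @param mu_tot Total dimensionless myosin \eqn{\mu_{tot} = \iint m\,d\omega}
#'   (conserved by the no-flux boundary condition).
#' @param v0 Dimensionless actin polymerization rate constant.
#' @param k Area-preservation strength of the protrusion law.
#' @param a0 Target dimensionless area (\eqn{\pi} for the unit-circle cell).
#' @param g Steepness of the initial linear myosin gradient, in \eqn{[-1, 1]};
#'   the initial condition is \eqn{m = (\mu_{tot}/|\omega|)(1 - g x)}.
#' @param mmax_u Crowding cutoff for advection: the effective advection
#'   velocity is `u * (1 - m/mmax_u)` for `m < mmax_u` and exactly zero
#'   otherwise.
#' @param mmax_d Crowding cutoff for diffusion (`mmax_u < mmax_d`).
#'
#' @return An object of class `"motility_params"`. The area exponent `n_exp`
#'   of the protrusion law is derived from the variant (2 for ZS, 0 for ZV).
#' @export
#' @examples
#' p <- motility_params("ZS", mu_tot = 1.5 * pi)
#' p$beta
motility_params <- function(variant = c("ZS", "ZV"), alpha = 0.5, beta = 5,
                            mu_tot = 1.5 * pi, v0 = 2.5, k = 1.5, a0 = pi,
                            g = 0.2, mmax_u = 15, mmax_d = 125) {
  variant <- match.arg(variant)
  stop_if_not_positive <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      stop("parameter '", name, "' must be a positive finite scalar",
           call. = FALSE)
    }
  }
  for (nm in c("alpha", "beta", "mu_tot", "a0", "mmax_u", "mmax_d")) {
    stop_if_not_positive(get(nm), nm)
  }
  if (!is.numeric(v0) || v0 < 0) stop("'v0' must be >= 0", call. = FALSE)
  if (!is.numeric(k) || k < 0) stop("'k' must be >= 0", call. = FALSE)
  if (!is.numeric(g) || abs(g) > 1) {
    stop("'g' must lie in [-1, 1]", call. = FALSE)
  }
  if (mmax_u >= mmax_d) stop("'mmax_u' must be < 'mmax_d'", call. = FALSE)
  structure(
    list(variant = variant, alpha = alpha, beta = beta, mu_tot = mu_tot,
         v0 = v0, k = k, a0 = a0, g = g, mmax_u = mmax_u, mmax_d = mmax_d,
         n_exp = if (variant == "ZS") 2L else 0L),
    class = "motility_params"
  )
}

#' @export
print.motility_params <- function(x, ...) {
  cat("<motility_params> variant =", x$variant, "\n")
  cat(sprintf("  alpha = %g, beta = %g, mu_tot = %g (= %g pi), v0 = %g\n",
              x$alpha, x$beta, x$mu_tot, x$mu_tot / pi, x$v0))
  cat(sprintf("  k = %g, a0 = %g, g = %g, mmax_u = %g, mmax_d = %g\n",
              x$k, x$a0, x$g, x$mmax_u, x$mmax_d))
  invisible(x)
}

#' Dimensional model parameters
#'
#' Physical parameters of the actomyosin model before nondimensionalization.
#' The length unit is the radius of the circle with the target area,
#' \eqn{L = \sqrt{A_0/\pi}}; time is measured in units of \eqn{L^2/D} and
#' myosin in units of the inhibition threshold \eqn{M_0}.
#'
#' @param eta Effective 2D actin network viscosity (force x time / length).
#' @param sigma Contractile force per unit myosin density.
#' @param xi Adhesion (viscous drag) coefficient.
#' @param D Myosin diffusivity (length^2 / time).
#' @param M0 Myosin concentration unit (protrusion-inhibition threshold).
#' @param V0 Actin growth rate constant (length / time).
#' @param K Area sensitivity of the protrusion rate.
#' @param A0 Target cell area (length^2).
#' @param Mmax_u,Mmax_d Dimensional crowding cutoffs, `Mmax_u < Mmax_d`.
#'
#' @return An object of class `"dimensional_params"` (also records
#'   `L = sqrt(A0/pi)`).
#' @seealso [nondimensionalize()]
#' @export
dimensional_params <- function(eta, sigma, xi, D, M0, V0, K, A0,
                               Mmax_u, Mmax_d) {
  vals <- list(eta = eta, sigma = sigma, xi = xi, D = D, M0 = M0, V0 = V0,
               K = K, A0 = A0, Mmax_u = Mmax_u, Mmax_d = Mmax_d)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("dimensional parameter '", nm, "' must be a positive finite scalar",
           call. = FALSE)
    }
  }
  if (Mmax_u >= Mmax_d) stop("'Mmax_u' must be < 'Mmax_d'", call. = FALSE)
  vals$L <- sqrt(A0 / pi)
  structure(vals, class = "dimensional_params")
}

#' Map dimensional to dimensionless parameters
#'
#' Applies the scaling with length unit \eqn{L = \sqrt{A_0/\pi}}, time unit
#' \eqn{L^2/D} and concentration unit \eqn{M_0}:
#' \eqn{\alpha = \eta L^{-2}\xi^{-1}}, \eqn{\beta = \sigma M_0 (D\xi)^{-1}},
#' \eqn{v_0 = V_0 L/D}, \eqn{k = K L^3/D}, \eqn{a_0 = A_0/L^2} and
#' \eqn{m_{max} = M_{max}/M_0}.
#'
#' @param p A [dimensional_params()] object.
#' @param variant Boundary-condition variant of the resulting model.
#' @param g Initial myosin gradient steepness (carried through unchanged).
#' @return A [motility_params()] object. `mu_tot` is derived from the uniform
#'   reference state \eqn{m = 1} over the target area, i.e.
#'   `mu_tot = a0`; set it explicitly afterwards for other myosin loads.
#' @export
nondimensionalize <- function(p, variant = c("ZS", "ZV"), g = 0.2) {
  if (!inherits(p, "dimensional_params")) {
    stop("'p' must be a dimensional_params object", call. = FALSE)
  }
  variant <- match.arg(variant)
  L <- p$L
  motility_params(
    variant = variant,
    alpha = p$eta / (L^2 * p$xi),
    beta = p$sigma * p$M0 / (p$D * p$xi),
    mu_tot = p$A0 / L^2,
    v0 = p$V0 * L / p$D,
    k = p$K * L^3 / p$D,
    a0 = p$A0 / L^2,
    g = g,
    mmax_u = p$Mmax_u / p$M0,
    mmax_d = p$Mmax_d / p$M0
  )
}

#' Crowding-limited effective advection factor
#'
#' Myosin crowding shuts down advection as the density approaches the cutoff:
#' the factor is `1 - m/mmax_u` below the cutoff and exactly zero at or above
#' it (the effective velocity is `u_eff = u * effective_advection_factor(m)`).
#'
#' @param m Myosin density (vectorized, must be non-negative).
#' @param mmax_u Advection crowding cutoff.
#' @return Values in `[0, 1]`, non-increasing in `m`.
#' @export
#' @examples
#' effective_advection_factor(c(0, 7.5, 15, 30), mmax_u = 15)
effective_advection_factor <- function(m, mmax_u = 15) {
  if (any(m < 0)) stop("myosin density must be non-negative", call. = FALSE)
  ifelse(m < mmax_u, 1 - m / mmax_u, 0)
}

#' Crowding-limited effective diffusivity
#'
#' Returns `1 - m/mmax_d`, floored at `d_floor` to keep the transport operator
#' parabolic should the density ever exceed the diffusion cutoff (the cutoff
#' is chosen above any density reached in valid runs, so the floor firing
#' indicates a run outside the intended regime and a warning is emitted).
#'
#' @param m Myosin density (vectorized, non-negative).
#' @param mmax_d Diffusion crowding cutoff.
#' @param d_floor Lower bound for the diffusivity factor.
#' @return Values in `[d_floor, 1]`, non-increasing in `m`.
#' @export
effective_diffusivity <- function(m, mmax_d = 125, d_floor = 1e-6) {
  if (any(m < 0)) stop("myosin density must be non-negative", call. = FALSE)
  d <- 1 - m / mmax_d
  if (any(d < d_floor)) {
    warning("effective diffusivity floored at ", d_floor,
            "; myosin density exceeded mmax_d", call. = FALSE)
    d <- pmax(d, d_floor)
  }
  d
}

variant_code <- function(variant) {
  if (identical(variant, "ZV")) 0L else 1L
}
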