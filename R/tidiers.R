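#' Tidy a simulation into its diagnostics table
#'
#' @param x A [run_simulation()] result.
#' @param ... Unused.
#' @return The diagnostics tibble (one row per step).
#' @export
tidy.cell_simulation <- function(x, ...) {
  x$diagnostics
}

#' One-row summary of a simulation
#'
#' @param x A [run_simulation()] result.
#' @param ... Unused.
#' @return A one-row tibble: classified state, steady metrics, myosin
#'   conservation drift and the maximum fixed-point iteration count.
#' @export
glance.cell_simulation <- function(x, ...) {
  d <- x$diagnostics
  lab <- tryCatch(classify_state(d),
                  actomotion_unresolved = function(e) NULL)
  mu <- x$params$mu_tot
  base <- tibble::tibble(
    variant = x$params$variant, alpha = x$params$alpha, v0 = x$params$v0,
    mu_tot = mu, t_end = max(d$t),
    state = if (is.null(lab)) "unresolved" else lab$state,
    speed = if (is.null(lab)) NA_real_ else lab$steady_speed,
    aspect_ratio = if (is.null(lab)) NA_real_ else lab$aspect_ratio,
    area = if (is.null(lab)) NA_real_ else lab$area,
    radius = if (is.null(lab)) NA_real_ else lab$radius,
    time_to_steady = if (is.null(lab)) NA_real_ else lab$time_to_steady,
    myosin_drift = max(abs(d$total_myosin - mu)) / mu,
    max_fp_iters = max(d$fp_iters, na.rm = TRUE))
  base
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
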