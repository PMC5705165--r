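#' Plot a simulated cell: shape, myosin and trajectory
#'
#' @param object A [run_simulation()] result.
#' @param ... Unused.
#' @return A ggplot object showing the final cell outline, the myosin density
#'   of the active cells, and the centroid track.
#' @export
autoplot.cell_simulation <- function(object, ...) {
  st <- object$state
  mk <- as.data.frame(st$curve$markers)
  names(mk) <- c("x", "y")
  mk <- rbind(mk, mk[1L, ])
  cells <- data.frame(x = st$mesh$gcx, y = st$mesh$gcy, m = st$m)
  traj <- object$diagnostics
  ggplot2::ggplot() +
    ggplot2::geom_tile(data = cells,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    fill = .data$m),
                       width = st$mesh$h, height = st$mesh$h) +
    ggplot2::geom_path(data = mk, ggplot2::aes(x = .data$x, y = .data$y),
                       linewidth = 0.4) +
    ggplot2::geom_path(data = traj,
                       ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "red", linetype = "22") +
    ggplot2::scale_fill_viridis_c(name = "myosin") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s model, t = %.2f",
                                  object$params$variant, st$t))
}

#' Plot diagnostics time series of a simulation
#'
#' @param sim A [run_simulation()] result.
#' @param vars Diagnostics columns to show.
#' @return A faceted ggplot of the selected series.
#' @export
plot_diagnostics <- function(sim, vars = c("speed", "aspect_ratio", "area",
                                           "total_myosin")) {
  d <- sim$diagnostics
  long <- do.call(rbind, lapply(vars, function(v) {
    data.frame(t = d$t, value = d[[v]], variable = v)
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "dimensionless time", y = NULL)
}

#' Phase-diagram plot of a parameter scan
#'
#' @param object An [phase_scan()] result.
#' @param ... Unused.
#' @return A ggplot mapping `v0` and `mu_tot/pi` to the classified state, one
#'   facet per `alpha`.
#' @export
autoplot.actomotion_scan <- function(object, ...) {
  d <- as.data.frame(object)
  d$mu_over_pi <- d$mu_tot / pi
  ggplot2::ggplot(d, ggplot2::aes(x = .data$v0, y = .data$mu_over_pi,
                                  colour = .data$state,
                                  shape = .data$ambiguous)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::facet_wrap(~alpha, labeller = ggplot2::label_both) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1)) +
    ggplot2::labs(x = expression(v[0]), y = expression(mu[tot] / pi),
                  colour = "state", shape = "ambiguous")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
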