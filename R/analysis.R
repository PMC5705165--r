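#' Algebraic circle fit to a centroid track
#'
#' Least-squares (Kasa) circle fit. A total-least-squares straight line is
#' fitted alongside; when the line residual is smaller than the circle
#' residual the track is deemed straight and the radius reported as `Inf`.
#'
#' @param x,y Centroid coordinates (at least 10 points spanning at least one
#'   time unit when called from the classifier).
#' @return List with `center`, `radius` (possibly `Inf`), `rms` (residual of
#'   the selected model), `rms_circle`, `rms_line`.
#' @export
fit_rotation_circle <- function(x, y) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  A <- cbind(x, y, 1)
  b <- x^2 + y^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  rms_circle <- Inf
  center <- c(NA_real_, NA_real_)
  radius <- Inf
  if (!is.null(sol)) {
    sol <- unname(sol)
    center <- c(sol[1] / 2, sol[2] / 2)
    r2 <- sol[3] + sum(center^2)
    if (is.finite(r2) && r2 > 0) {
      radius <- sqrt(r2)
      d <- sqrt((x - center[1])^2 + (y - center[2])^2)
      rms_circle <- sqrt(mean((d - radius)^2))
    }
  }
  # total least squares line through the centroid of the points
  mx <- mean(x); my <- mean(y)
  M <- cbind(x - mx, y - my)
  sv <- svd(M)
  rms_line <- sv$d[2] / sqrt(n)
  if (rms_line <= rms_circle) {
    list(center = c(NA_real_, NA_real_), radius = Inf, rms = rms_line,
         rms_circle = rms_circle, rms_line = rms_line)
  } else {
    list(center = center, radius = radius, rms = rms_circle,
         rms_circle = rms_circle, rms_line = rms_line)
  }
}

#' Detect the onset of steady motion
#'
#' The documented steadiness criterion: the earliest time after which the
#' centroid speed and the aspect ratio each stay within `rel_tol` (default
#' 2\%) of their trailing-window means, for a trailing window of `window`
#' (default 5) time units, through the end of the record. Near-zero mean
#' speeds use the absolute floor `abs_floor` so that stationary cells
#' register as steady.
#'
#' @param record Diagnostics tibble with columns `t`, `speed`, `aspect_ratio`.
#' @param window Trailing window length (time units).
#' @param rel_tol Relative band around the window mean.
#' @param abs_floor Speed scale below which the band becomes absolute
#'   (`rel_tol * abs_floor`), so that stationary cells register as steady.
#' @param smooth Width (time units) of the centered moving average applied to
#'   the speed and aspect-ratio series before banding; rotating cells carry a
#'   sub-period oscillation as they cross the background grid, and steadiness
#'   concerns the envelope (0 disables).
#' @return The steadiness onset time (start of the first all-steady window),
#'   or `NA` if never reached.
#' @export
detect_steady <- function(record, window = 5, rel_tol = 0.02,
                          abs_floor = 0.05, smooth = 1) {
  t <- record$t
  sp <- record$speed
  ar <- record$aspect_ratio
  if (smooth > 0 && length(t) > 3L) {
    # centered moving average over `smooth` time units: the band applies to
    # the envelope of the motion, not to sub-period oscillations (rotating
    # cells cross the background grid periodically)
    sp <- running_mean_t(t, sp, smooth)
    ar <- running_mean_t(t, ar, smooth)
  }
  ok <- rep(NA, length(t))
  i0 <- which(t >= t[1] + window)
  if (length(i0) == 0L) return(NA_real_)
  for (i in i0) {
    sel <- which(t > t[i] - window & t <= t[i])
    sel <- sel[is.finite(sp[sel])]
    if (length(sel) < 10L) { ok[i] <- FALSE; next }
    ms <- mean(sp[sel]); ma <- mean(ar[sel])
    tol_s <- rel_tol * max(ms, abs_floor)
    tol_a <- rel_tol * ma
    ok[i] <- all(abs(sp[sel] - ms) <= tol_s) && all(abs(ar[sel] - ma) <= tol_a)
  }
  idx <- i0[!is.na(ok[i0])]
  if (length(idx) == 0L) return(NA_real_)
  flags <- ok[idx]
  # first index from which all later windows are steady
  suffix_all <- rev(cumprod(rev(flags))) > 0
  if (!any(suffix_all)) return(NA_real_)
  j <- idx[which(suffix_all)[1L]]
  t[j] - window
}

# centered moving average over a time window (irregular sampling supported)
running_mean_t <- function(t, v, width) {
  n <- length(t)
  out <- v
  j0 <- 1L
  j1 <- 1L
  csum <- cumsum(ifelse(is.finite(v), v, 0))
  cnt <- cumsum(as.numeric(is.finite(v)))
  for (i in seq_len(n)) {
    while (t[j0] < t[i] - width / 2) j0 <- j0 + 1L
    while (j1 < n && t[j1 + 1L] <= t[i] + width / 2) j1 <- j1 + 1L
    num <- csum[j1] - if (j0 > 1L) csum[j0 - 1L] else 0
    den <- cnt[j1] - if (j0 > 1L) cnt[j0 - 1L] else 0
    if (den > 0) out[i] <- num / den
  }
  out
}

#' Classify the asymptotic mechanical state
#'
#' Labels a trajectory as `stationary`, `translation` or `rotation` from its
#' trailing window. A cell is stationary when the trailing mean speed falls
#' below `1e-2` of the maximum historical speed and the net displacement over
#' the window is below 0.1; otherwise the centroid track is circle-fitted and
#' the state is a rotation when the fitted radius is at most
#' `r_factor * sqrt(a/pi)` (radius of rotation comparable to, or smaller
#' than, the cell's linear size), else a translation. Rotations whose radius
#' lies within 50\% of the threshold are flagged ambiguous, mirroring the
#' gradual translation-to-rotation crossover.
#'
#' @param record Diagnostics tibble (columns `t`, `x`, `y`, `area`, `speed`,
#'   `aspect_ratio`).
#' @param window Trailing window (time units).
#' @param r_factor Size factor defining "comparable to the cell size".
#' @param require_steady Error (class `actomotion_unresolved`) when the
#'   steadiness criterion was not met, instead of silently labelling.
#' @return A list of class `"state_label"`: `state`, `steady_speed`,
#'   `aspect_ratio`, `area`, `time_to_steady`, `ambiguous`, and for rotations
#'   `radius` and `angular_velocity`.
#' @export
classify_state <- function(record, window = 5, r_factor = 1.5,
                           require_steady = TRUE) {
  ts <- detect_steady(record, window = window)
  if (require_steady && !is.finite(ts)) {
    stop(structure(class = c("actomotion_unresolved", "error", "condition"),
                   list(message = "record did not reach steadiness; classification unresolved",
                        call = NULL)))
  }
  t <- record$t
  sel <- which(t > max(t) - window)
  sel <- sel[is.finite(record$speed[sel])]
  sp <- mean(record$speed[sel])
  v_ref <- max(record$speed, na.rm = TRUE)
  a <- mean(record$area[sel])
  ar <- mean(record$aspect_ratio[sel])
  size <- sqrt(a / pi)
  net <- sqrt((record$x[max(sel)] - record$x[min(sel)])^2 +
              (record$y[max(sel)] - record$y[min(sel)])^2)
  sp <- unname(sp)
  out <- list(state = "translation", steady_speed = sp, aspect_ratio = ar,
              area = a, time_to_steady = ts, ambiguous = FALSE,
              radius = Inf, angular_velocity = 0)
  if (sp <= 1e-2 * max(v_ref, 1e-8) && net < 0.1) {
    out$state <- "stationary"
    out$angular_velocity <- NA_real_
    out$radius <- NA_real_
  } else {
    fit <- fit_rotation_circle(record$x[sel], record$y[sel])
    thr <- r_factor * size
    if (is.finite(fit$radius) && fit$radius <= thr) {
      out$state <- "rotation"
      out$radius <- fit$radius
      out$angular_velocity <- sp / fit$radius
      out$ambiguous <- fit$radius > 0.75 * thr
    } else if (is.finite(fit$radius) && fit$radius <= 1.5 * thr) {
      out$ambiguous <- TRUE
    }
  }
  class(out) <- "state_label"
  out
}

#' @export
print.state_label <- function(x, ...) {
  cat("<state_label>", x$state,
      if (isTRUE(x$ambiguous)) "(ambiguous)" else "", "\n")
  cat(sprintf("  speed %.4f, aspect ratio %.3f, area %.4f, time-to-steady %.3f\n",
              x$steady_speed, x$aspect_ratio, x$area, x$time_to_steady))
  if (identical(x$state, "rotation")) {
    cat(sprintf("  rotation radius %.3f, angular velocity %.4f\n",
                x$radius, x$angular_velocity))
  }
  invisible(x)
}

#' Steady-state trajectory metrics
#'
#' Trailing-window means of speed, aspect ratio and area, plus the angular
#' velocity (`speed / radius` for rotations, 0 for translations) and the
#' detected time-to-steady.
#'
#' @inheritParams classify_state
#' @return A one-row tibble.
#' @export
steady_metrics <- function(record, window = 5, r_factor = 1.5) {
  lab <- classify_state(record, window = window, r_factor = r_factor)
  tibble::tibble(
    state = lab$state, speed = lab$steady_speed,
    angular_velocity = lab$angular_velocity, radius = lab$radius,
    aspect_ratio = lab$aspect_ratio, area = lab$area,
    time_to_steady = lab$time_to_steady, ambiguous = lab$ambiguous)
}

#' Phase-diagram parameter scan
#'
#' Runs one simulation per parameter tuple and tabulates the classified
#' states. Duplicate tuples are deduplicated deterministically; records that
#' never reach steadiness are labelled `"unresolved"` rather than silently
#' classified.
#'
#' @param variant `"ZS"` or `"ZV"`.
#' @param v0_values,mu_tot_values,alpha_values Scan grids.
#' @param settings A [solver_settings()] object.
#' @param base Base [motility_params()] supplying the fixed parameters.
#' @param stop_when_steady Stop each run early once steady (default `TRUE`).
#' @return A tibble of class `"actomotion_scan"` with columns `variant`,
#'   `alpha`, `v0`, `mu_tot`, `state`, `speed`, `radius`, `omega`,
#'   `aspect_ratio`, `area`, `ambiguous`.
#' @export
phase_scan <- function(variant, v0_values, mu_tot_values, alpha_values = 0.5,
                       settings = solver_settings(),
                       base = motility_params(variant),
                       stop_when_steady = TRUE) {
  grid <- expand.grid(alpha = alpha_values, v0 = v0_values,
                      mu_tot = mu_tot_values, KEEP.OUT.ATTRS = FALSE)
  grid <- unique(grid[order(grid$alpha, grid$v0, grid$mu_tot), , drop = FALSE])
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- base
    p$alpha <- grid$alpha[i]
    p$v0 <- grid$v0[i]
    p$mu_tot <- grid$mu_tot[i]
    sim <- run_simulation(p, settings, stop_when_steady = stop_when_steady)
    lab <- tryCatch(classify_state(sim$diagnostics),
                    actomotion_unresolved = function(e) NULL)
    if (is.null(lab)) {
      tibble::tibble(variant = variant, alpha = p$alpha, v0 = p$v0,
                     mu_tot = p$mu_tot, state = "unresolved",
                     speed = NA_real_, radius = NA_real_, omega = NA_real_,
                     aspect_ratio = NA_real_, area = NA_real_,
                     ambiguous = TRUE)
    } else {
      tibble::tibble(variant = variant, alpha = p$alpha, v0 = p$v0,
                     mu_tot = p$mu_tot, state = lab$state,
                     speed = lab$steady_speed, radius = lab$radius,
                     omega = lab$angular_velocity,
                     aspect_ratio = lab$aspect_ratio, area = lab$area,
                     ambiguous = lab$ambiguous)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- tibble::tibble(variant = character(), alpha = numeric(),
                          v0 = numeric(), mu_tot = numeric(),
                          state = character(), speed = numeric(),
                          radius = numeric(), omega = numeric(),
                          aspect_ratio = numeric(), area = numeric(),
                          ambiguous = logical())
  }
  class(out) <- c("actomotion_scan", class(out))
  out
}

#' Synthetic centroid tracks for classifier validation
#'
#' Generates idealized stationary, straight or circular centroid records
#' (optionally with Gaussian jitter) in the same tibble layout as simulation
#' diagnostics; used to validate the classifier independently of the solver.
#'
#' @param kind `"stationary"`, `"translation"` or `"rotation"`.
#' @param t_end,dt Time grid.
#' @param speed Centroid speed (translation/rotation).
#' @param radius Rotation radius.
#' @param area,aspect Constant shape metrics for the record.
#' @param noise_sd Gaussian position jitter (uses the current RNG state).
#' @return A diagnostics tibble.
#' @export
synthetic_track <- function(kind = c("stationary", "translation", "rotation"),
                            t_end = 20, dt = 0.05, speed = 1, radius = 0.8,
                            area = pi, aspect = 2, noise_sd = 0) {
  kind <- match.arg(kind)
  t <- seq(0, t_end, by = dt)
  if (kind == "stationary") {
    x <- rep(0, length(t)); y <- rep(0, length(t)); sp <- rep(0, length(t))
    aspect <- 1
  } else if (kind == "translation") {
    x <- speed * t; y <- rep(0, length(t)); sp <- rep(speed, length(t))
  } else {
    om <- speed / radius
    x <- radius * cos(om * t); y <- radius * sin(om * t)
    sp <- rep(speed, length(t))
  }
  if (noise_sd > 0) {
    x <- x + stats::rnorm(length(t), 0, noise_sd)
    y <- y + stats::rnorm(length(t), 0, noise_sd)
    sp[-1L] <- sqrt(diff(x)^2 + diff(y)^2) / dt
  }
  tibble::tibble(t = t, x = x, y = y, area = area, speed = sp,
                 aspect_ratio = aspect, total_myosin = NA_real_,
                 fp_iters = NA_real_, max_m = NA_real_)
}
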