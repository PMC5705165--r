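#' Closed boundary curve of the moving cell
#'
#' A boundary curve is a closed, counterclockwise, simple marker polygon
#' representing the cell edge \eqn{\partial\omega(t)}. Markers are stored as
#' an `n x 2` matrix without repeating the first point.
#'
#' @param markers Numeric `n x 2` matrix of marker coordinates (dimensionless
#'   length units), ordered counterclockwise.
#' @param target_spacing Desired arclength between markers after resampling;
#'   defaults to the current mean spacing.
#' @param validate Check simplicity and orientation (default `TRUE`).
#' @return An object of class `"boundary_curve"`.
#' @export
boundary_curve <- function(markers, target_spacing = NULL, validate = TRUE) {
  markers <- as.matrix(markers)
  if (ncol(markers) != 2L || nrow(markers) < 8L) {
    stop("'markers' must be an n x 2 matrix with n >= 8", call. = FALSE)
  }
  if (anyNA(markers)) stop("markers contain NA", call. = FALSE)
  storage.mode(markers) <- "double"
  a <- polygon_area_cpp(markers)
  if (validate) {
    if (a <= 0) {
      stop("boundary curve must be counterclockwise (positive enclosed area)",
           call. = FALSE)
    }
    if (curve_self_intersects_cpp(markers)) {
      stop("boundary curve is self-intersecting", call. = FALSE)
    }
  }
  if (is.null(target_spacing)) {
    d <- sqrt(rowSums((markers[c(2:nrow(markers), 1L), ] - markers)^2))
    target_spacing <- mean(d)
  }
  structure(list(markers = markers, target_spacing = target_spacing),
            class = "boundary_curve")
}

#' @export
print.boundary_curve <- function(x, ...) {
  cat(sprintf("<boundary_curve> %d markers, area %.5f, spacing %.4g\n",
              nrow(x$markers), enclosed_area(x), x$target_spacing))
  invisible(x)
}

#' Unit-circle (or general circular) boundary curve
#'
#' @param radius Circle radius.
#' @param center Length-2 center.
#' @param n Number of markers.
#' @param target_spacing Optional resampling target spacing.
#' @return A [boundary_curve()].
#' @export
circle_curve <- function(radius = 1, center = c(0, 0), n = 256,
                         target_spacing = NULL) {
  th <- 2 * pi * seq(0L, n - 1L) / n
  boundary_curve(cbind(center[1] + radius * cos(th),
                       center[2] + radius * sin(th)),
                 target_spacing = target_spacing)
}

#' Enclosed area of a boundary curve
#'
#' Shoelace polygon area; positive for the counterclockwise curves used
#' throughout.
#' @param curve A [boundary_curve()].
#' @return Positive scalar area.
#' @export
enclosed_area <- function(curve) {
  a <- polygon_area_cpp(curve$markers)
  if (a <= 0) stop("curve has non-positive area", call. = FALSE)
  a
}

#' Centroid of the enclosed region
#'
#' Area-weighted polygon centroid.
#' @param curve A [boundary_curve()].
#' @return Length-2 numeric vector.
#' @export
curve_centroid <- function(curve) {
  polygon_centroid_cpp(curve$markers)
}

#' Aspect ratio of the cell shape
#'
#' Ratio of the longest to the shortest distance between the boundary and the
#' cell centroid; 1 for a circle.
#' @param curve A [boundary_curve()].
#' @return Scalar `>= 1`.
#' @export
aspect_ratio <- function(curve) {
  cc <- curve_centroid(curve)
  r <- sqrt((curve$markers[, 1] - cc[1])^2 + (curve$markers[, 2] - cc[2])^2)
  max(r) / min(r)
}

#' Outward unit normals at markers
#'
#' Normals from central-difference tangents, rotated to point outward for the
#' counterclockwise orientation. Outwardness is verified by an in/out probe at
#' a sample of markers rather than assumed from convexity.
#'
#' @param curve A [boundary_curve()].
#' @param verify Probe-check outwardness (default `TRUE`).
#' @return `n x 2` matrix of unit normals.
#' @export
outward_normals <- function(curve, verify = TRUE) {
  nm <- outward_normals_cpp(curve$markers)
  if (verify) {
    n <- nrow(nm)
    idx <- unique(round(seq(1L, n, length.out = min(16L, n))))
    eps <- 0.05 * curve$target_spacing
    probe_out <- curve$markers[idx, , drop = FALSE] + eps * nm[idx, , drop = FALSE]
    probe_in <- curve$markers[idx, , drop = FALSE] - eps * nm[idx, , drop = FALSE]
    ok <- !points_in_polygon_cpp(probe_out, curve$markers) &
      points_in_polygon_cpp(probe_in, curve$markers)
    if (mean(ok) < 0.75) {
      stop("outward normal verification failed; curve may be degenerate",
           call. = FALSE)
    }
  }
  nm
}

#' Uniform protrusion rate of the ZS model
#'
#' \eqn{v_p = v_0 a_0/a - k\,(a - a_0 (a_0/a)^2)}. The first term is actin
#' growth diluted by cell spreading; the second combines membrane tension
#' (which stops expansion for `a > a0`) with a quadratic cytoplasmic
#' resistance that prevents collapse for small `a` even when `v0 = 0`.
#'
#' @param a Current dimensionless area (`> 0`).
#' @param p A [motility_params()] object.
#' @return Scalar protrusion speed, uniform along the boundary.
#' @export
protrusion_rate_zs <- function(a, p) {
  if (!is.numeric(a) || any(a <= 0)) stop("area must be positive", call. = FALSE)
  p$v0 * p$a0 / a - p$k * (a - p$a0 * (p$a0 / a)^2)
}

#' Myosin-inhibited protrusion rate of the ZV model
#'
#' \eqn{v_p = v_0 a_0 / (a (1 + m_b)) - k (a - a_0)} where `m_b` is the
#' myosin density extrapolated to the boundary point: local myosin inhibits
#' actin growth, which is what couples the interior dynamics to the boundary
#' in the ZV model (the actin flow vanishes at the edge there).
#'
#' @param a Current dimensionless area (`> 0`).
#' @param m_b Boundary myosin density per marker (non-negative, vectorized).
#' @param p A [motility_params()] object.
#' @return Protrusion speed per marker.
#' @export
protrusion_rate_zv <- function(a, m_b, p) {
  if (!is.numeric(a) || any(a <= 0)) stop("area must be positive", call. = FALSE)
  if (any(m_b < 0)) stop("boundary myosin must be non-negative", call. = FALSE)
  p$v0 * p$a0 / (a * (1 + m_b)) - p$k * (a - p$a0)
}

#' Assemble the boundary velocity field
#'
#' The boundary moves with the superposition of normal protrusion and the
#' actin flow at the edge: \eqn{v_f = v_p n + u|_{\partial\omega}}. In the ZV
#' model the actin velocity vanishes at the boundary, so a nonzero `u_b` is a
#' contract violation there.
#'
#' @param curve A [boundary_curve()].
#' @param v_p Protrusion speed, scalar or per-marker vector.
#' @param u_b `n x 2` actin velocity at markers, or `NULL` (zero).
#' @param variant `"ZS"` or `"ZV"`.
#' @return An object of class `"boundary_velocity"` with fields `v_p`, `u_b`,
#'   `v_f` (n x 2) and `normals`.
#' @export
assemble_boundary_velocity <- function(curve, v_p, u_b = NULL,
                                       variant = c("ZS", "ZV")) {
  variant <- match.arg(variant)
  n <- nrow(curve$markers)
  v_p <- rep_len(v_p, n)
  if (is.null(u_b)) u_b <- matrix(0, n, 2)
  u_b <- as.matrix(u_b)
  if (nrow(u_b) != n || ncol(u_b) != 2L) {
    stop("'u_b' must align with the markers", call. = FALSE)
  }
  if (variant == "ZV" && any(u_b != 0)) {
    stop("ZV model has zero actin velocity at the boundary; supplied u_b must be zero",
         call. = FALSE)
  }
  nm <- outward_normals(curve, verify = FALSE)
  structure(list(v_p = v_p, u_b = u_b, v_f = v_p * nm + u_b, normals = nm),
            class = "boundary_velocity")
}

#' Resample a curve to uniform marker spacing
#'
#' Arclength reparameterization through a periodic cubic spline; the marker
#' count adapts to keep spacing near `target_spacing`.
#'
#' @param curve A [boundary_curve()].
#' @return A resampled [boundary_curve()] with the same `target_spacing`.
#' @export
resample_curve <- function(curve) {
  rs <- resample_curve_cpp(curve$markers, curve$target_spacing)
  boundary_curve(rs$markers, target_spacing = curve$target_spacing,
                 validate = FALSE)
}

#' Advance the front by one time step
#'
#' Moves every marker by `dt * v_f` and resamples to the target spacing.
#' Sharpening concave corners (the rear of fast cells) form front shocks
#' where neighboring marker paths cross; such local micro-loops are clipped
#' at the crossing point (the entropy-consistent front position), mirroring
#' what robust front trackers do. Any remaining -- i.e. non-local --
#' self-intersection is a hard topology error: the model never splits or
#' merges cells. Resampling is required to change the enclosed area by no
#' more than `1e-3` of the current area.
#'
#' @param curve A [boundary_curve()].
#' @param bv A [assemble_boundary_velocity()] result.
#' @param dt Positive time step.
#' @return The advanced, resampled [boundary_curve()].
#' @export
advance_front <- function(curve, bv, dt) {
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be positive", call. = FALSE)
  moved <- curve$markers + dt * bv$v_f
  if (curve_self_intersects_cpp(moved)) {
    moved <- untangle_local_cpp(moved)$markers
    if (curve_self_intersects_cpp(moved)) {
      stop("front self-intersected during advance (topology error)",
           call. = FALSE)
    }
  }
  a_moved <- polygon_area_cpp(moved)
  rs <- resample_curve_cpp(moved, curve$target_spacing)
  a_new <- polygon_area_cpp(rs$markers)
  if (abs(a_new - a_moved) > 1e-3 * abs(a_moved)) {
    stop("resampling changed the enclosed area by more than 1e-3 relative",
         call. = FALSE)
  }
  out <- boundary_curve(rs$markers, target_spacing = curve$target_spacing,
                        validate = FALSE)
  if (curve_self_intersects_cpp(out$markers)) {
    stop("front self-intersected after resampling (topology error)",
         call. = FALSE)
  }
  out
}
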