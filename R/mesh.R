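#' Cut-cell finite-volume mesh of the moving domain
#'
#' Builds a mass-conservative finite-volume mesh of the region enclosed by a
#' boundary curve on a fixed Cartesian background grid. Cells fully inside the
#' domain carry volume fraction 1, cells crossed by the boundary carry their
#' exact clipped fraction and face apertures, and small cut cells (fraction
#' below `merge_thresh`) are merged with a neighboring host cell for solver
#' purposes; the merge is recorded in the cell-to-unknown index map `grp`.
#'
#' The background grid is global (cell `(i, j)` covers
#' `[i*h, (i+1)*h] x [j*h, (j+1)*h]`), so meshes built for successive boundary
#' positions share the grid and exchange mass exactly via [transfer_mass()].
#'
#' @param curve A [boundary_curve()].
#' @param h Grid spacing, in `[0.01, 0.5]`.
#' @param merge_thresh Volume-fraction threshold below which cut cells are
#'   merged with a neighbor (default 0.3).
#' @return An object of class `"motile_mesh"`: the window origin/extent, the
#'   volume-fraction matrix `f`, face apertures `ax`/`ay`, group index map
#'   `grp`, per-group volumes, centroids and boundary-segment data (length,
#'   midpoint, integrated outward normal), the group-to-group face list, and
#'   the total `area`.
#' @export
build_mesh <- function(curve, h, merge_thresh = 0.3) {
  if (!inherits(curve, "boundary_curve")) {
    stop("'curve' must be a boundary_curve", call. = FALSE)
  }
  if (!is.numeric(h) || h < 0.01 || h > 0.5) {
    stop("'h' must lie in [0.01, 0.5]", call. = FALSE)
  }
  m <- mesh_build_cpp(curve$markers, h, merge_thresh)
  m$merge_thresh <- merge_thresh
  class(m) <- "motile_mesh"
  m
}

#' @export
print.motile_mesh <- function(x, ...) {
  cat(sprintf("<motile_mesh> h = %g, %d x %d window, %d unknowns, area %.5f\n",
              x$h, x$nx, x$ny, x$G, x$area))
  invisible(x)
}

#' Second-order bilinear extrapolation to boundary points
#'
#' Evaluates a cell-centered field at points on (or near) the domain boundary
#' by fitting a bilinear function over the nearest fully interior 2x2 cell
#' stencil found along the inward normal and extrapolating it to the point;
#' exact for affine fields. Where no complete interior stencil exists within
#' three grid spacings, the nearest active cell value is used and counted in
#' the `n_fallback` attribute.
#'
#' @param mesh A [build_mesh()] result.
#' @param values Field values per mesh unknown (length `mesh$G`).
#' @param points `P x 2` matrix of evaluation points.
#' @param normals `P x 2` outward unit normals at the points (used by the
#'   bilinear method to search inward for its stencil).
#' @param method `"ls"` (default): weighted least-squares plane
#'   reconstruction over the active cells (cut cells included) within a few
#'   grid spacings of the point -- continuous in the point position and
#'   wall-attached, which matters where the field has steep boundary-normal
#'   gradients. `"bilinear"`: bilinear fit over the nearest fully interior
#'   2x2 stencil along the inward normal. Both are exact for affine fields
#'   and second-order accurate.
#' @return Numeric vector of length `P` with attribute `n_fallback`.
#' @export
extrapolate_to_boundary <- function(mesh, values, points, normals = NULL,
                                    method = c("ls", "bilinear")) {
  method <- match.arg(method)
  if (length(values) != mesh$G) {
    stop("'values' must have one entry per mesh unknown", call. = FALSE)
  }
  points <- as.matrix(points)
  if (method == "bilinear") {
    if (is.null(normals)) {
      stop("the bilinear method needs outward normals", call. = FALSE)
    }
    r <- extrap_boundary_cpp(mesh, as.numeric(values), points,
                             as.matrix(normals))
  } else {
    r <- extrap_boundary_ls_cpp(mesh, as.numeric(values), points)
  }
  out <- r$values
  attr(out, "n_fallback") <- r$n_fallback
  out
}

#' Exactly conservative mass transfer between meshes
#'
#' Redistributes cell masses from an old mesh onto a new mesh sharing the same
#' background grid. Cells active in both meshes keep their mass; cells that
#' dried donate their mass to wetted neighbors weighted by the connecting
#' apertures; the global mass is conserved to round-off for any motion of at
#' most one cell per step.
#'
#' @param m_old Field values per old-mesh unknown (density, not mass).
#' @param mesh_old,mesh_new Meshes from [build_mesh()] on the same grid.
#' @return List with `m` (density per new-mesh unknown) and `mass` (mass per
#'   new-mesh unknown; `sum(mass)` equals the old total mass).
#' @export
transfer_mass <- function(m_old, mesh_old, mesh_new) {
  if (abs(mesh_old$h - mesh_new$h) > 1e-14) {
    stop("meshes must share the background grid spacing", call. = FALSE)
  }
  r <- transfer_mass_cpp(mesh_old, mesh_new, as.numeric(m_old))
  if (r$lost != 0) {
    stop("mass transfer failed to place all mass (domain moved too far?)",
         call. = FALSE)
  }
  r[c("m", "mass")]
}

#' Total myosin on a mesh
#' @param mesh A [build_mesh()] result.
#' @param m Density per unknown.
#' @return Scalar \eqn{\sum m \cdot vol}.
#' @export
total_mass <- function(mesh, m) {
  sum(as.numeric(m) * mesh$gvol)
}

# centers of the active unknowns (volume-weighted member-cell centers)
mesh_centers <- function(mesh) {
  cbind(mesh$gcx, mesh$gcy)
}
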