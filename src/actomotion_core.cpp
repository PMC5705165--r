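// Computational core: polygon geometry, cut-cell mesh construction on a fixed
// Cartesian background grid, bilinear boundary extrapolation, periodic-spline
// front resampling, conservative inter-mesh mass transfer, and the coupled
// force-balance / myosin-transport solvers (segregated fixed point).
//
// Conventions:
//  * Boundary curves are closed CCW marker polygons, stored n x 2 (last row
//    is NOT a repeat of the first).
//  * Background cells are [i*h,(i+1)*h] x [j*h,(j+1)*h] in global indices;
//    a mesh stores a local window (ix0, iy0, nx, ny).
//  * ax is (nx+1) x ny (vertical faces, ax(i,j) = west face of local cell i),
//    ay is nx x (ny+1).
//  * variant: 0 = ZV (zero boundary velocity), 1 = ZS (zero boundary stress).

#include <RcppArmadillo.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// basic polygon helpers
// ---------------------------------------------------------------------------

static double shoelace(const NumericMatrix& p) {
  const int n = p.nrow();
  double a = 0.0;
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    a += p(i, 0) * p(j, 1) - p(j, 0) * p(i, 1);
  }
  return 0.5 * a;
}

// [[Rcpp::export]]
double polygon_area_cpp(NumericMatrix p) { return shoelace(p); }

// [[Rcpp::export]]
NumericVector polygon_centroid_cpp(NumericMatrix p) {
  const int n = p.nrow();
  double a = 0.0, cx = 0.0, cy = 0.0;
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    double cr = p(i, 0) * p(j, 1) - p(j, 0) * p(i, 1);
    a += cr;
    cx += (p(i, 0) + p(j, 0)) * cr;
    cy += (p(i, 1) + p(j, 1)) * cr;
  }
  a *= 0.5;
  NumericVector out(2);
  out[0] = cx / (6.0 * a);
  out[1] = cy / (6.0 * a);
  return out;
}

static bool point_in_poly(double x, double y, const NumericMatrix& p) {
  const int n = p.nrow();
  bool inside = false;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    double yi = p(i, 1), yj = p(j, 1);
    if ((yi > y) != (yj > y)) {
      double xint = p(j, 0) + (y - yj) * (p(i, 0) - p(j, 0)) / (yi - yj);
      if (x < xint) inside = !inside;
    }
  }
  return inside;
}

// [[Rcpp::export]]
LogicalVector points_in_polygon_cpp(NumericMatrix pts, NumericMatrix poly) {
  const int n = pts.nrow();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = point_in_poly(pts(i, 0), pts(i, 1), poly);
  return out;
}

// central-difference outward normals for a CCW closed polygon
// [[Rcpp::export]]
NumericMatrix outward_normals_cpp(NumericMatrix p) {
  const int n = p.nrow();
  NumericMatrix nm(n, 2);
  for (int i = 0; i < n; ++i) {
    int ip = (i + 1) % n, im = (i - 1 + n) % n;
    double tx = p(ip, 0) - p(im, 0);
    double ty = p(ip, 1) - p(im, 1);
    double nrm = std::sqrt(tx * tx + ty * ty);
    if (nrm < 1e-14) stop("degenerate (duplicate) markers in boundary curve");
    nm(i, 0) = ty / nrm;
    nm(i, 1) = -tx / nrm;
  }
  return nm;
}

// proper segment intersection test (shared endpoints of adjacent segments
// excluded by the caller)
static inline double orient(double ax, double ay, double bx, double by,
                            double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

static bool seg_intersect(double ax, double ay, double bx, double by,
                          double cx, double cy, double dx, double dy) {
  double d1 = orient(cx, cy, dx, dy, ax, ay);
  double d2 = orient(cx, cy, dx, dy, bx, by);
  double d3 = orient(ax, ay, bx, by, cx, cy);
  double d4 = orient(ax, ay, bx, by, dx, dy);
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
    return true;
  return false;
}

// [[Rcpp::export]]
bool curve_self_intersects_cpp(NumericMatrix p) {
  const int n = p.nrow();
  // bin segments on a coarse grid to avoid O(n^2)
  double minx = R_PosInf, miny = R_PosInf, maxx = R_NegInf, maxy = R_NegInf,
         maxlen = 0.0;
  for (int i = 0; i < n; ++i) {
    minx = std::min(minx, p(i, 0)); maxx = std::max(maxx, p(i, 0));
    miny = std::min(miny, p(i, 1)); maxy = std::max(maxy, p(i, 1));
    int j = (i + 1) % n;
    double dx = p(j, 0) - p(i, 0), dy = p(j, 1) - p(i, 1);
    maxlen = std::max(maxlen, std::sqrt(dx * dx + dy * dy));
  }
  double cs = std::max(maxlen * 2.0, 1e-12);
  int bx = std::max(1, (int)std::ceil((maxx - minx) / cs));
  int by = std::max(1, (int)std::ceil((maxy - miny) / cs));
  std::vector<std::vector<int>> bins((size_t)bx * by);
  auto binof = [&](double x, double y) {
    int ix = std::min(bx - 1, std::max(0, (int)((x - minx) / cs)));
    int iy = std::min(by - 1, std::max(0, (int)((y - miny) / cs)));
    return iy * bx + ix;
  };
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    double mx = 0.5 * (p(i, 0) + p(j, 0)), my = 0.5 * (p(i, 1) + p(j, 1));
    bins[binof(mx, my)].push_back(i);
  }
  for (int i = 0; i < n; ++i) {
    int i2 = (i + 1) % n;
    double mx = 0.5 * (p(i, 0) + p(i2, 0)), my = 0.5 * (p(i, 1) + p(i2, 1));
    int cx0 = std::max(0, (int)((mx - minx) / cs) - 1);
    int cy0 = std::max(0, (int)((my - miny) / cs) - 1);
    int cx1 = std::min(bx - 1, (int)((mx - minx) / cs) + 1);
    int cy1 = std::min(by - 1, (int)((my - miny) / cs) + 1);
    for (int iy = cy0; iy <= cy1; ++iy)
      for (int ix = cx0; ix <= cx1; ++ix)
        for (int k : bins[(size_t)iy * bx + ix]) {
          if (k <= i) continue;
          int k2 = (k + 1) % n;
          // skip adjacent segments (shared endpoint)
          if (k == i || k2 == i || k == i2) continue;
          if (seg_intersect(p(i, 0), p(i, 1), p(i2, 0), p(i2, 1),
                            p(k, 0), p(k, 1), p(k2, 0), p(k2, 1)))
            return true;
        }
  }
  return false;
}

// Remove local "swallowtail" micro-loops produced when marker paths cross in
// a sharpening concave corner (the front shock of normal-driven motion):
// crossings between segments at most max_gap markers apart are clipped at
// the intersection point, which is the entropy-consistent front position.
// Non-local crossings are left for the caller to treat as topology errors.
// [[Rcpp::export]]
List untangle_local_cpp(NumericMatrix p, int max_gap = 12) {
  std::vector<std::array<double, 2>> pts;
  for (int i = 0; i < p.nrow(); ++i) pts.push_back({p(i, 0), p(i, 1)});
  int removed = 0;
  bool changed = true;
  int guard = 0;
  while (changed && guard++ < 50) {
    changed = false;
    const int n = (int)pts.size();
    if (n < 8) break;
    for (int i = 0; i < n && !changed; ++i) {
      for (int off = 2; off <= max_gap && !changed; ++off) {
        int k = (i + off) % n;
        int i2 = (i + 1) % n, k2 = (k + 1) % n;
        if (k2 == i) continue;
        if (seg_intersect(pts[i][0], pts[i][1], pts[i2][0], pts[i2][1],
                          pts[k][0], pts[k][1], pts[k2][0], pts[k2][1])) {
          // intersection point of the two segments
          double x1 = pts[i][0], y1 = pts[i][1], x2 = pts[i2][0],
                 y2 = pts[i2][1];
          double x3 = pts[k][0], y3 = pts[k][1], x4 = pts[k2][0],
                 y4 = pts[k2][1];
          double den = (x1 - x2) * (y3 - y4) - (y1 - y2) * (x3 - x4);
          double tpar = ((x1 - x3) * (y3 - y4) - (y1 - y3) * (x3 - x4)) / den;
          double xi = x1 + tpar * (x2 - x1), yi = y1 + tpar * (y2 - y1);
          // drop markers i+1 .. k (the loop), insert the crossing point;
          // keep the original marker order and start index so the
          // resampling anchor is not rotated by the clip
          std::vector<bool> drop(n, false);
          for (int q = (i + 1) % n; q != (k + 1) % n; q = (q + 1) % n)
            drop[q] = true;
          std::vector<std::array<double, 2>> np;
          np.reserve(n);
          for (int q = 0; q < n; ++q) {
            if (!drop[q]) np.push_back(pts[q]);
            if (q == i) np.push_back({xi, yi});
          }
          removed += n - (int)np.size();
          pts.swap(np);
          changed = true;
        }
      }
    }
  }
  NumericMatrix out((int)pts.size(), 2);
  for (size_t i = 0; i < pts.size(); ++i) {
    out((int)i, 0) = pts[i][0];
    out((int)i, 1) = pts[i][1];
  }
  return List::create(_["markers"] = out, _["removed"] = removed);
}

// ---------------------------------------------------------------------------
// periodic cubic spline resampling by arclength
// ---------------------------------------------------------------------------

// cyclic tridiagonal solve (Sherman-Morrison); a = sub, b = diag, c = super
static std::vector<double> cyclic_tridiag(const std::vector<double>& a,
                                          const std::vector<double>& b,
                                          const std::vector<double>& c,
                                          const std::vector<double>& d) {
  const int n = (int)b.size();
  std::vector<double> bb(b), u(n, 0.0), x(n), z(n);
  double alpha = a[0], beta = c[n - 1];
  double gamma = -b[0];
  bb[0] = b[0] - gamma;
  bb[n - 1] = b[n - 1] - alpha * beta / gamma;
  auto thomas = [&](const std::vector<double>& rhs, std::vector<double>& out) {
    std::vector<double> cp(n), dp(n);
    cp[0] = c[0] / bb[0];
    dp[0] = rhs[0] / bb[0];
    for (int i = 1; i < n; ++i) {
      double m = bb[i] - a[i] * cp[i - 1];
      cp[i] = c[i] / m;
      dp[i] = (rhs[i] - a[i] * dp[i - 1]) / m;
    }
    out[n - 1] = dp[n - 1];
    for (int i = n - 2; i >= 0; --i) out[i] = dp[i] - cp[i] * out[i + 1];
  };
  thomas(d, x);
  std::vector<double> uvec(n, 0.0);
  uvec[0] = gamma;
  uvec[n - 1] = alpha;
  thomas(uvec, z);
  double fact = (x[0] + beta * x[n - 1] / gamma) /
                (1.0 + z[0] + beta * z[n - 1] / gamma);
  for (int i = 0; i < n; ++i) x[i] -= fact * z[i];
  return x;
}

struct PeriodicSpline {
  std::vector<double> t, y, M; // knots, values, second derivatives
  double period;
  void fit(const std::vector<double>& tk, const std::vector<double>& yk,
           double per) {
    t = tk; y = yk; period = per;
    const int n = (int)t.size();
    std::vector<double> a(n), b(n), c(n), d(n), h(n);
    for (int i = 0; i < n; ++i) {
      double tn = (i + 1 < n) ? t[i + 1] : t[0] + period;
      h[i] = tn - t[i];
    }
    for (int i = 0; i < n; ++i) {
      int im = (i - 1 + n) % n;
      a[i] = h[im] / 6.0;
      b[i] = (h[im] + h[i]) / 3.0;
      c[i] = h[i] / 6.0;
      double yi = y[i];
      double yn = y[(i + 1) % n];
      double yp = y[im];
      d[i] = (yn - yi) / h[i] - (yi - yp) / h[im];
    }
    M = cyclic_tridiag(a, b, c, d);
  }
  double eval(double s) const {
    const int n = (int)t.size();
    double w = (s - t[0]) / period;
    s = (w - std::floor(w)) * period + t[0];
    int lo = (int)(std::upper_bound(t.begin(), t.end(), s) - t.begin()) - 1;
    if (lo < 0) lo = 0;
    if (lo > n - 1) lo = n - 1;
    double t0 = t[lo];
    double t1 = (lo + 1 < n) ? t[lo + 1] : t[0] + period;
    double y0 = y[lo], y1 = y[(lo + 1) % n];
    double M0 = M[lo], M1 = M[(lo + 1) % n];
    double hh = t1 - t0;
    double A = (t1 - s) / hh, B = (s - t0) / hh;
    return A * y0 + B * y1 +
           ((A * A * A - A) * M0 + (B * B * B - B) * M1) * hh * hh / 6.0;
  }
};

// resample a closed CCW polygon to (approximately) equal arclength spacing
// [[Rcpp::export]]
List resample_curve_cpp(NumericMatrix p, double target_spacing,
                        int min_markers = 32, int max_markers = 8192) {
  const int n = p.nrow();
  std::vector<double> tk(n), xk(n), yk(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    xk[i] = p(i, 0);
    yk[i] = p(i, 1);
    tk[i] = acc;
    int j = (i + 1) % n;
    double dx = p(j, 0) - p(i, 0), dy = p(j, 1) - p(i, 1);
    acc += std::sqrt(dx * dx + dy * dy);
  }
  double chord_per = acc;
  PeriodicSpline sx, sy;
  sx.fit(tk, xk, chord_per);
  sy.fit(tk, yk, chord_per);
  // dense arclength table
  const int sub = 8;
  const int nd = n * sub;
  std::vector<double> ts(nd + 1), as(nd + 1);
  double alen = 0.0;
  double px = sx.eval(0.0), py = sy.eval(0.0);
  ts[0] = 0.0; as[0] = 0.0;
  for (int i = 1; i <= nd; ++i) {
    double tt = chord_per * (double)i / nd;
    double qx = sx.eval(tt), qy = sy.eval(tt);
    alen += std::sqrt((qx - px) * (qx - px) + (qy - py) * (qy - py));
    ts[i] = tt; as[i] = alen;
    px = qx; py = qy;
  }
  // even marker count so mirror-symmetric configurations stay exactly
  // representable (marker 0 anchors the symmetry axis)
  int nn = 2 * (int)std::lround(alen / target_spacing / 2.0);
  nn = std::max(min_markers, std::min(max_markers, nn));
  NumericMatrix out(nn, 2);
  int hint = 0;
  for (int i = 0; i < nn; ++i) {
    double starg = alen * (double)i / nn;
    while (hint < nd && as[hint + 1] < starg) ++hint;
    double w = (as[hint + 1] > as[hint])
                   ? (starg - as[hint]) / (as[hint + 1] - as[hint])
                   : 0.0;
    double tt = ts[hint] + w * (ts[hint + 1] - ts[hint]);
    out(i, 0) = sx.eval(tt);
    out(i, 1) = sy.eval(tt);
  }
  return List::create(_["markers"] = out, _["perimeter"] = alen);
}

// ---------------------------------------------------------------------------
// cut-cell mesh construction
// ---------------------------------------------------------------------------

// crossings of the polygon with the line {coord axis = val}; returns sorted
// intersection ordinates along the other axis
static std::vector<double> line_crossings(const NumericMatrix& p, int axis,
                                          double val) {
  const int n = p.nrow();
  std::vector<double> cr;
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    double a = p(i, axis), b = p(j, axis);
    if ((a < val) != (b < val)) {
      double w = (val - a) / (b - a);
      double o = p(i, 1 - axis) + w * (p(j, 1 - axis) - p(i, 1 - axis));
      cr.push_back(o);
    }
  }
  std::sort(cr.begin(), cr.end());
  return cr;
}

// overlap of union of [cr[2k], cr[2k+1]] with [lo, hi]
static double interval_overlap(const std::vector<double>& cr, double lo,
                               double hi) {
  double tot = 0.0;
  for (size_t k = 0; k + 1 < cr.size(); k += 2) {
    double a = std::max(cr[k], lo), b = std::min(cr[k + 1], hi);
    if (b > a) tot += b - a;
  }
  return tot;
}

// Sutherland-Hodgman clip of polygon against axis-aligned rectangle; returns
// clipped area
static double clip_area_rect(const NumericMatrix& p, double x0, double x1,
                             double y0, double y1) {
  std::vector<std::array<double, 2>> poly;
  poly.reserve(p.nrow() + 8);
  for (int i = 0; i < p.nrow(); ++i) poly.push_back({p(i, 0), p(i, 1)});
  auto clip = [&](int axis, double bound, int keep_sign) {
    std::vector<std::array<double, 2>> out;
    const int m = (int)poly.size();
    if (m == 0) return out;
    out.reserve(m + 4);
    for (int i = 0; i < m; ++i) {
      auto& P = poly[i];
      auto& Q = poly[(i + 1) % m];
      double dP = keep_sign * (P[axis] - bound);
      double dQ = keep_sign * (Q[axis] - bound);
      bool inP = dP >= 0.0, inQ = dQ >= 0.0;
      if (inP) out.push_back(P);
      if (inP != inQ) {
        double w = dP / (dP - dQ);
        std::array<double, 2> X;
        X[axis] = bound;
        X[1 - axis] = P[1 - axis] + w * (Q[1 - axis] - P[1 - axis]);
        out.push_back(X);
      }
    }
    return out;
  };
  poly = clip(0, x0, +1);
  poly = clip(0, x1, -1);
  poly = clip(1, y0, +1);
  poly = clip(1, y1, -1);
  double a = 0.0;
  const int m = (int)poly.size();
  for (int i = 0; i < m; ++i) {
    int j = (i + 1) % m;
    a += poly[i][0] * poly[j][1] - poly[j][0] * poly[i][1];
  }
  return 0.5 * a;
}

// Liang-Barsky clip of segment to rectangle; returns t0,t1 in [0,1] or false
static bool clip_seg_rect(double px, double py, double qx, double qy,
                          double x0, double x1, double y0, double y1,
                          double& t0, double& t1) {
  double dx = qx - px, dy = qy - py;
  t0 = 0.0; t1 = 1.0;
  double pcl[4] = {-dx, dx, -dy, dy};
  double qcl[4] = {px - x0, x1 - px, py - y0, y1 - py};
  for (int k = 0; k < 4; ++k) {
    if (std::fabs(pcl[k]) < 1e-300) {
      if (qcl[k] < 0) return false;
    } else {
      double r = qcl[k] / pcl[k];
      if (pcl[k] < 0) {
        if (r > t1) return false;
        if (r > t0) t0 = r;
      } else {
        if (r < t0) return false;
        if (r < t1) t1 = r;
      }
    }
  }
  return t1 > t0;
}

// [[Rcpp::export]]
List mesh_build_cpp(NumericMatrix mk, double h, double merge_thresh = 0.3,
                    double active_eps = 1e-9) {
  const int n = mk.nrow();
  double minx = R_PosInf, miny = R_PosInf, maxx = R_NegInf, maxy = R_NegInf;
  for (int i = 0; i < n; ++i) {
    minx = std::min(minx, mk(i, 0)); maxx = std::max(maxx, mk(i, 0));
    miny = std::min(miny, mk(i, 1)); maxy = std::max(maxy, mk(i, 1));
  }
  if (maxx - minx < 2.0 * h || maxy - miny < 2.0 * h)
    stop("boundary curve is smaller than two grid cells; decrease h");
  const int ix0 = (int)std::floor(minx / h) - 2;
  const int iy0 = (int)std::floor(miny / h) - 2;
  const int nx = ((int)std::floor(maxx / h) + 2) - ix0 + 1;
  const int ny = ((int)std::floor(maxy / h) + 2) - iy0 + 1;
  const double X0 = ix0 * h, Y0 = iy0 * h;

  NumericMatrix ax(nx + 1, ny), ay(nx, ny + 1);
  // vertical faces
  for (int i = 0; i <= nx; ++i) {
    std::vector<double> cr = line_crossings(mk, 0, X0 + i * h);
    if (cr.empty()) continue;
    for (int j = 0; j < ny; ++j)
      ax(i, j) = interval_overlap(cr, Y0 + j * h, Y0 + (j + 1) * h) / h;
  }
  // horizontal faces
  for (int j = 0; j <= ny; ++j) {
    std::vector<double> cr = line_crossings(mk, 1, Y0 + j * h);
    if (cr.empty()) continue;
    for (int i = 0; i < nx; ++i)
      ay(i, j) = interval_overlap(cr, X0 + i * h, X0 + (i + 1) * h) / h;
  }
  // cell-center classification per row
  LogicalMatrix inside(nx, ny);
  for (int j = 0; j < ny; ++j) {
    std::vector<double> cr = line_crossings(mk, 1, Y0 + (j + 0.5) * h);
    if (cr.empty()) continue;
    for (int i = 0; i < nx; ++i) {
      double xc = X0 + (i + 0.5) * h;
      int cnt = 0;
      for (double c : cr)
        if (xc < c) ++cnt;
      inside(i, j) = (cnt % 2) == 1;
    }
  }
  // volume fractions
  NumericMatrix f(nx, ny);
  const double tol1 = 1e-12;
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      double aw = ax(i, j), ae = ax(i + 1, j), as = ay(i, j), an = ay(i, j + 1);
      bool all1 = aw > 1.0 - tol1 && ae > 1.0 - tol1 && as > 1.0 - tol1 &&
                  an > 1.0 - tol1;
      bool all0 = aw < tol1 && ae < tol1 && as < tol1 && an < tol1;
      if (all1) {
        f(i, j) = 1.0;
      } else if (all0) {
        f(i, j) = inside(i, j) ? 1.0 : 0.0;
      } else {
        double a = clip_area_rect(mk, X0 + i * h, X0 + (i + 1) * h,
                                  Y0 + j * h, Y0 + (j + 1) * h) / (h * h);
        f(i, j) = std::min(1.0, std::max(0.0, a));
      }
    }
  }
  // boundary polyline pieces per cell
  NumericMatrix blen(nx, ny), bpx(nx, ny), bpy(nx, ny);
  for (int e = 0; e < n; ++e) {
    int e2 = (e + 1) % n;
    double px = mk(e, 0), py = mk(e, 1), qx = mk(e2, 0), qy = mk(e2, 1);
    int ia = std::max(0, (int)std::floor((std::min(px, qx) - X0) / h));
    int ib = std::min(nx - 1, (int)std::floor((std::max(px, qx) - X0) / h));
    int ja = std::max(0, (int)std::floor((std::min(py, qy) - Y0) / h));
    int jb = std::min(ny - 1, (int)std::floor((std::max(py, qy) - Y0) / h));
    double elen = std::sqrt((qx - px) * (qx - px) + (qy - py) * (qy - py));
    for (int j = ja; j <= jb; ++j)
      for (int i = ia; i <= ib; ++i) {
        double t0, t1;
        if (clip_seg_rect(px, py, qx, qy, X0 + i * h, X0 + (i + 1) * h,
                          Y0 + j * h, Y0 + (j + 1) * h, t0, t1)) {
          double L = (t1 - t0) * elen;
          double mx = px + 0.5 * (t0 + t1) * (qx - px);
          double my = py + 0.5 * (t0 + t1) * (qy - py);
          blen(i, j) += L;
          bpx(i, j) += L * mx;
          bpy(i, j) += L * my;
        }
      }
  }
  // group assignment with small-cell merging
  IntegerMatrix grp(nx, ny); // 0 = inactive, else group id (1-based)
  int G = 0;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      if (f(i, j) >= merge_thresh) grp(i, j) = ++G;
  // iterative attachment of small active cells
  bool changed = true;
  int passes = 0;
  while (changed && passes < 64) {
    changed = false;
    ++passes;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (grp(i, j) != 0 || f(i, j) <= active_eps) continue;
        int best = 0;
        double bestw = -1.0;
        struct Nb { int gi; double w; };
        // candidate neighbors: (aperture, group)
        int gi; double w;
        if (i > 0 && (gi = grp(i - 1, j)) != 0) {
          w = ax(i, j) + 1e-9 * f(i - 1, j);
          if (w > bestw) { bestw = w; best = gi; }
        }
        if (i < nx - 1 && (gi = grp(i + 1, j)) != 0) {
          w = ax(i + 1, j) + 1e-9 * f(i + 1, j);
          if (w > bestw) { bestw = w; best = gi; }
        }
        if (j > 0 && (gi = grp(i, j - 1)) != 0) {
          w = ay(i, j) + 1e-9 * f(i, j - 1);
          if (w > bestw) { bestw = w; best = gi; }
        }
        if (j < ny - 1 && (gi = grp(i, j + 1)) != 0) {
          w = ay(i, j + 1) + 1e-9 * f(i, j + 1);
          if (w > bestw) { bestw = w; best = gi; }
        }
        if (best != 0 && bestw > 0.0) {
          grp(i, j) = best;
          changed = true;
        }
      }
  }
  // leftovers become their own groups (isolated slivers)
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      if (grp(i, j) == 0 && f(i, j) > active_eps) grp(i, j) = ++G;

  // group accumulators
  NumericVector gvol(G), gcx(G), gcy(G), gblen(G), gbpx(G), gbpy(G), gNx(G),
      gNy(G);
  LogicalVector gcut(G);
  const double h2 = h * h;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int g = grp(i, j);
      if (g == 0) continue;
      double vol = f(i, j) * h2;
      gvol[g - 1] += vol;
      gcx[g - 1] += vol * (X0 + (i + 0.5) * h);
      gcy[g - 1] += vol * (Y0 + (j + 0.5) * h);
      gblen[g - 1] += blen(i, j);
      gbpx[g - 1] += bpx(i, j);
      gbpy[g - 1] += bpy(i, j);
      gNx[g - 1] += h * (ax(i, j) - ax(i + 1, j));
      gNy[g - 1] += h * (ay(i, j) - ay(i, j + 1));
    }
  for (int g = 0; g < G; ++g) {
    if (gvol[g] > 0) { gcx[g] /= gvol[g]; gcy[g] /= gvol[g]; }
    if (gblen[g] > 1e-14) {
      gbpx[g] /= gblen[g];
      gbpy[g] /= gblen[g];
      gcut[g] = true;
    }
  }
  // face list between distinct groups
  std::vector<int> fa, fb_, fdir;
  std::vector<double> fap;
  for (int j = 0; j < ny; ++j)
    for (int i = 1; i < nx; ++i) {
      double a = ax(i, j);
      if (a <= 1e-12) continue;
      int gA = grp(i - 1, j), gB = grp(i, j);
      if (gA == 0 || gB == 0 || gA == gB) continue;
      fa.push_back(gA); fb_.push_back(gB); fap.push_back(a); fdir.push_back(0);
    }
  for (int j = 1; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double a = ay(i, j);
      if (a <= 1e-12) continue;
      int gA = grp(i, j - 1), gB = grp(i, j);
      if (gA == 0 || gB == 0 || gA == gB) continue;
      fa.push_back(gA); fb_.push_back(gB); fap.push_back(a); fdir.push_back(1);
    }
  const int NF = (int)fa.size();
  IntegerMatrix faces(NF, 3);
  NumericVector faper(NF);
  for (int k = 0; k < NF; ++k) {
    faces(k, 0) = fa[k];
    faces(k, 1) = fb_[k];
    faces(k, 2) = fdir[k];
    faper[k] = fap[k];
  }
  double area = 0.0;
  for (int g = 0; g < G; ++g) area += gvol[g];

  return List::create(
      _["h"] = h, _["ix0"] = ix0, _["iy0"] = iy0, _["nx"] = nx, _["ny"] = ny,
      _["f"] = f, _["ax"] = ax, _["ay"] = ay, _["grp"] = grp, _["G"] = G,
      _["gvol"] = gvol, _["gcx"] = gcx, _["gcy"] = gcy, _["gblen"] = gblen,
      _["gbpx"] = gbpx, _["gbpy"] = gbpy, _["gNx"] = gNx, _["gNy"] = gNy,
      _["gcut"] = gcut, _["faces"] = faces, _["faper"] = faper,
      _["area"] = area);
}

// ---------------------------------------------------------------------------
// bilinear boundary extrapolation
// ---------------------------------------------------------------------------

struct MeshView {
  double h, X0, Y0;
  int nx, ny, G;
  NumericMatrix f;
  IntegerMatrix grp;
  NumericVector gvol, gcx, gcy, gblen, gbpx, gbpy, gNx, gNy;
  LogicalVector gcut;
  IntegerMatrix faces;
  NumericVector faper;
  explicit MeshView(const List& m)
      : h(as<double>(m["h"])),
        X0(as<int>(m["ix0"]) * as<double>(m["h"])),
        Y0(as<int>(m["iy0"]) * as<double>(m["h"])),
        nx(as<int>(m["nx"])), ny(as<int>(m["ny"])), G(as<int>(m["G"])),
        f(as<NumericMatrix>(m["f"])), grp(as<IntegerMatrix>(m["grp"])),
        gvol(as<NumericVector>(m["gvol"])), gcx(as<NumericVector>(m["gcx"])),
        gcy(as<NumericVector>(m["gcy"])),
        gblen(as<NumericVector>(m["gblen"])),
        gbpx(as<NumericVector>(m["gbpx"])),
        gbpy(as<NumericVector>(m["gbpy"])), gNx(as<NumericVector>(m["gNx"])),
        gNy(as<NumericVector>(m["gNy"])), gcut(as<LogicalVector>(m["gcut"])),
        faces(as<IntegerMatrix>(m["faces"])),
        faper(as<NumericVector>(m["faper"])) {}
  bool full_cell(int i, int j) const {
    return i >= 0 && j >= 0 && i < nx && j < ny && f(i, j) >= 0.999999;
  }
};

// extrapolate group-valued field to boundary points; returns values and the
// number of fallback (nearest-cell) evaluations
static void extrap_points(const MeshView& mv, const arma::vec& gv,
                          const NumericMatrix& pts, const NumericMatrix& nrm,
                          arma::vec& out, int& nfallback) {
  const int P = pts.nrow();
  const double h = mv.h;
  nfallback = 0;
  for (int p = 0; p < P; ++p) {
    double pxx = pts(p, 0), pyy = pts(p, 1);
    double nxv = nrm(p, 0), nyv = nrm(p, 1);
    bool done = false;
    for (double kk : {1.0, 1.5, 2.0, 2.5, 3.0}) {
      double qx = pxx - kk * h * nxv, qy = pyy - kk * h * nyv;
      double fi = (qx - mv.X0) / h - 0.5, fj = (qy - mv.Y0) / h - 0.5;
      int i0 = (int)std::floor(fi), j0 = (int)std::floor(fj);
      if (mv.full_cell(i0, j0) && mv.full_cell(i0 + 1, j0) &&
          mv.full_cell(i0, j0 + 1) && mv.full_cell(i0 + 1, j0 + 1)) {
        double tx = (pxx - mv.X0) / h - 0.5 - i0;
        double ty = (pyy - mv.Y0) / h - 0.5 - j0;
        double v00 = gv[mv.grp(i0, j0) - 1];
        double v10 = gv[mv.grp(i0 + 1, j0) - 1];
        double v01 = gv[mv.grp(i0, j0 + 1) - 1];
        double v11 = gv[mv.grp(i0 + 1, j0 + 1) - 1];
        out[p] = (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
                 (1 - tx) * ty * v01 + tx * ty * v11;
        done = true;
        break;
      }
    }
    if (!done) {
      // nearest active cell center
      ++nfallback;
      double best = R_PosInf;
      double val = 0.0;
      int ic = (int)std::floor((pxx - mv.X0) / h);
      int jc = (int)std::floor((pyy - mv.Y0) / h);
      for (int r = 0; r <= std::max(mv.nx, mv.ny); ++r) {
        bool found = false;
        for (int j = std::max(0, jc - r); j <= std::min(mv.ny - 1, jc + r); ++j)
          for (int i = std::max(0, ic - r); i <= std::min(mv.nx - 1, ic + r);
               ++i) {
            if (mv.grp(i, j) == 0) continue;
            double dx = mv.X0 + (i + 0.5) * h - pxx;
            double dy = mv.Y0 + (j + 0.5) * h - pyy;
            double d2 = dx * dx + dy * dy;
            if (d2 < best) {
              best = d2;
              val = gv[mv.grp(i, j) - 1];
              found = true;
            }
          }
        if (found && r >= 2) break;
      }
      out[p] = val;
    }
  }
}

// weighted least-squares plane reconstruction from nearby active cells
// (cut cells included, so the sampled values stay attached to the wall);
// exact for affine fields, continuous in the point position
static void extrap_points_ls(const MeshView& mv, const arma::vec& gv,
                             const NumericMatrix& pts, arma::vec& out,
                             int& nfallback) {
  const int P = pts.nrow();
  const double h = mv.h;
  nfallback = 0;
  for (int p = 0; p < P; ++p) {
    double pxx = pts(p, 0), pyy = pts(p, 1);
    bool done = false;
    for (double R : {2.5 * h, 3.5 * h, 5.0 * h}) {
      int i0 = std::max(0, (int)std::floor((pxx - R - mv.X0) / h));
      int i1 = std::min(mv.nx - 1, (int)std::floor((pxx + R - mv.X0) / h));
      int j0 = std::max(0, (int)std::floor((pyy - R - mv.Y0) / h));
      int j1 = std::min(mv.ny - 1, (int)std::floor((pyy + R - mv.Y0) / h));
      // normal equations for value + gradient at the point, one entry per
      // group (members accumulated by volume to avoid double counting)
      std::vector<int> gs;
      std::vector<double> gw, gx_, gy_;
      std::vector<int> seen(mv.G, -1);
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) {
          int g = mv.grp(i, j);
          if (g == 0) continue;
          if (seen[g - 1] < 0) {
            double dx = mv.gcx[g - 1] - pxx, dy = mv.gcy[g - 1] - pyy;
            double d = std::sqrt(dx * dx + dy * dy);
            if (d > R) continue;
            double w = (1.0 - d / R);
            w = w * w * mv.gvol[g - 1];
            seen[g - 1] = (int)gs.size();
            gs.push_back(g - 1);
            gw.push_back(w);
            gx_.push_back(dx);
            gy_.push_back(dy);
          }
        }
      if ((int)gs.size() < 4) continue;
      arma::mat N(3, 3, arma::fill::zeros);
      arma::vec b(3, arma::fill::zeros);
      for (size_t k = 0; k < gs.size(); ++k) {
        double w = gw[k], x = gx_[k], y = gy_[k], v = gv[gs[k]];
        N(0, 0) += w;        N(0, 1) += w * x;      N(0, 2) += w * y;
        N(1, 1) += w * x * x; N(1, 2) += w * x * y; N(2, 2) += w * y * y;
        b[0] += w * v;       b[1] += w * x * v;     b[2] += w * y * v;
      }
      N(1, 0) = N(0, 1); N(2, 0) = N(0, 2); N(2, 1) = N(1, 2);
      arma::vec sol;
      if (arma::solve(sol, N, b, arma::solve_opts::no_approx)) {
        out[p] = sol[0];
        done = true;
        break;
      }
    }
    if (!done) {
      ++nfallback;
      // nearest active cell center
      double best = R_PosInf, val = 0.0;
      for (int j = 0; j < mv.ny; ++j)
        for (int i = 0; i < mv.nx; ++i) {
          int g = mv.grp(i, j);
          if (g == 0) continue;
          double dx = mv.gcx[g - 1] - pxx, dy = mv.gcy[g - 1] - pyy;
          double d2 = dx * dx + dy * dy;
          if (d2 < best) { best = d2; val = gv[g - 1]; }
        }
      out[p] = val;
    }
  }
}

// [[Rcpp::export]]
List extrap_boundary_ls_cpp(List mesh, NumericVector gvals,
                            NumericMatrix pts) {
  MeshView mv(mesh);
  arma::vec gv(gvals.begin(), gvals.size());
  arma::vec out(pts.nrow());
  int nfb = 0;
  extrap_points_ls(mv, gv, pts, out, nfb);
  return List::create(_["values"] = NumericVector(out.begin(), out.end()),
                      _["n_fallback"] = nfb);
}

// [[Rcpp::export]]
List extrap_boundary_cpp(List mesh, NumericVector gvals, NumericMatrix pts,
                         NumericMatrix nrm) {
  MeshView mv(mesh);
  arma::vec gv(gvals.begin(), gvals.size());
  arma::vec out(pts.nrow());
  int nfb = 0;
  extrap_points(mv, gv, pts, nrm, out, nfb);
  return List::create(_["values"] = NumericVector(out.begin(), out.end()),
                      _["n_fallback"] = nfb);
}

// ---------------------------------------------------------------------------
// conservative mass transfer between meshes sharing the background grid
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List transfer_mass_cpp(List mesh_old, List mesh_new, NumericVector m_old) {
  MeshView mo(mesh_old), mn(mesh_new);
  if (std::fabs(mo.h - mn.h) > 1e-14)
    stop("meshes must share the background grid");
  const double h2 = mo.h * mo.h;
  const int oix0 = (int)std::lround(mo.X0 / mo.h);
  const int oiy0 = (int)std::lround(mo.Y0 / mo.h);
  const int nix0 = (int)std::lround(mn.X0 / mn.h);
  const int niy0 = (int)std::lround(mn.Y0 / mn.h);
  arma::vec gmass(mn.G, arma::fill::zeros);
  double lost = 0.0;

  auto new_f = [&](int gi, int gj) -> double { // global cell indices
    int i = gi - nix0, j = gj - niy0;
    if (i < 0 || j < 0 || i >= mn.nx || j >= mn.ny) return 0.0;
    return mn.f(i, j);
  };
  auto new_grp = [&](int gi, int gj) -> int {
    int i = gi - nix0, j = gj - niy0;
    if (i < 0 || j < 0 || i >= mn.nx || j >= mn.ny) return 0;
    return mn.grp(i, j);
  };

  for (int j = 0; j < mo.ny; ++j)
    for (int i = 0; i < mo.nx; ++i) {
      int g = mo.grp(i, j);
      if (g == 0) continue;
      double mass = m_old[g - 1] * mo.f(i, j) * h2;
      if (mass == 0.0) continue;
      int gi = i + oix0, gj = j + oiy0;
      int ng = new_grp(gi, gj);
      if (ng != 0 && new_f(gi, gj) > 0) {
        gmass[ng - 1] += mass;
      } else {
        // dried cell: donate to wetted neighbors weighted by old apertures
        double w[4];
        int nb[4][2] = {{gi - 1, gj}, {gi + 1, gj}, {gi, gj - 1}, {gi, gj + 1}};
        w[0] = mo.f(i, j) > 0 && i > 0 ? as<NumericMatrix>(mesh_old["ax"])(i, j) : 0.0;
        w[1] = i < mo.nx - 1 ? as<NumericMatrix>(mesh_old["ax"])(i + 1, j) : 0.0;
        w[2] = j > 0 ? as<NumericMatrix>(mesh_old["ay"])(i, j) : 0.0;
        w[3] = j < mo.ny - 1 ? as<NumericMatrix>(mesh_old["ay"])(i, j + 1) : 0.0;
        double tot = 0.0;
        for (int k = 0; k < 4; ++k) {
          if (new_grp(nb[k][0], nb[k][1]) == 0) w[k] = 0.0;
          tot += w[k];
        }
        if (tot <= 0) { // fall back to plain wetted-neighbor weights
          for (int k = 0; k < 4; ++k) {
            w[k] = new_f(nb[k][0], nb[k][1]);
            tot += w[k];
          }
        }
        if (tot > 0) {
          for (int k = 0; k < 4; ++k)
            if (w[k] > 0)
              gmass[new_grp(nb[k][0], nb[k][1]) - 1] += mass * w[k] / tot;
        } else {
          // nearest wetted cell in the new mesh (rare)
          double best = R_PosInf;
          int bg = 0;
          for (int jj = 0; jj < mn.ny; ++jj)
            for (int ii = 0; ii < mn.nx; ++ii) {
              if (mn.grp(ii, jj) == 0) continue;
              double dx = (ii + nix0) - gi, dy = (jj + niy0) - gj;
              double d2 = dx * dx + dy * dy;
              if (d2 < best) { best = d2; bg = mn.grp(ii, jj); }
            }
          if (bg != 0) gmass[bg - 1] += mass;
          else lost += mass;
        }
      }
    }
  arma::vec mg(mn.G);
  for (int g = 0; g < mn.G; ++g)
    mg[g] = mn.gvol[g] > 0 ? gmass[g] / mn.gvol[g] : 0.0;
  return List::create(_["mass"] = NumericVector(gmass.begin(), gmass.end()),
                      _["m"] = NumericVector(mg.begin(), mg.end()),
                      _["lost"] = lost);
}

// volume-weighted (non-conservative) transfer of per-group column fields to a
// new mesh sharing the background grid; used only to seed iterates
// [[Rcpp::export]]
NumericMatrix transfer_field_cpp(List mesh_old, List mesh_new,
                                 NumericMatrix vals) {
  MeshView mo(mesh_old), mn(mesh_new);
  const int oix0 = (int)std::lround(mo.X0 / mo.h);
  const int oiy0 = (int)std::lround(mo.Y0 / mo.h);
  const int nix0 = (int)std::lround(mn.X0 / mn.h);
  const int niy0 = (int)std::lround(mn.Y0 / mn.h);
  const int nc = vals.ncol();
  NumericMatrix acc(mn.G, nc);
  std::vector<double> wsum(mn.G, 0.0);
  for (int j = 0; j < mn.ny; ++j)
    for (int i = 0; i < mn.nx; ++i) {
      int g = mn.grp(i, j);
      if (g == 0) continue;
      int oi = i + nix0 - oix0, oj = j + niy0 - oiy0;
      if (oi < 0 || oj < 0 || oi >= mo.nx || oj >= mo.ny) continue;
      int og = mo.grp(oi, oj);
      if (og == 0) continue;
      double w = mn.f(i, j);
      wsum[g - 1] += w;
      for (int c = 0; c < nc; ++c) acc(g - 1, c) += w * vals(og - 1, c);
    }
  for (int g = 0; g < mn.G; ++g)
    if (wsum[g] > 0)
      for (int c = 0; c < nc; ++c) acc(g, c) /= wsum[g];
  return acc;
}

// ---------------------------------------------------------------------------
// force balance and transport assembly
// ---------------------------------------------------------------------------

static inline double adv_factor(double m, double mmax_u) {
  return (m < mmax_u) ? (1.0 - m / mmax_u) : 0.0;
}
static inline double diff_factor(double m, double mmax_d, double d_floor) {
  return std::max(1.0 - m / mmax_d, d_floor);
}

// assemble the (shared per-component) force-balance matrix A = alpha*L - V
static arma::mat fb_matrix(const MeshView& mv, double alpha, int variant) {
  const int G = mv.G;
  const double h = mv.h;
  arma::mat A(G, G, arma::fill::zeros);
  for (int g = 0; g < G; ++g) A(g, g) = -mv.gvol[g];
  for (int k = 0; k < mv.faces.nrow(); ++k) {
    int gA = mv.faces(k, 0) - 1, gB = mv.faces(k, 1) - 1;
    double c = alpha * mv.faper[k];
    A(gA, gA) -= c; A(gA, gB) += c;
    A(gB, gB) -= c; A(gB, gA) += c;
  }
  if (variant == 0) { // ZV: Dirichlet u = 0 on the front via one-sided flux
    for (int g = 0; g < G; ++g) {
      if (!mv.gcut[g] || mv.gblen[g] <= 0) continue;
      double Nn = std::sqrt(mv.gNx[g] * mv.gNx[g] + mv.gNy[g] * mv.gNy[g]);
      double nxv = Nn > 0 ? mv.gNx[g] / Nn : 0.0;
      double nyv = Nn > 0 ? mv.gNy[g] / Nn : 0.0;
      double db = (mv.gbpx[g] - mv.gcx[g]) * nxv +
                  (mv.gbpy[g] - mv.gcy[g]) * nyv;
      db = std::max(db, 0.25 * h);
      A(g, g) -= alpha * mv.gblen[g] / db;
    }
  }
  return A;
}

// right-hand sides (x and y) for given myosin iterate; mb = boundary myosin
// per group (ZV only)
static void fb_rhs(const MeshView& mv, const arma::vec& m, double beta,
                   int variant, const arma::vec& mb, arma::vec& rx,
                   arma::vec& ry) {
  const double h = mv.h;
  rx.zeros(mv.G);
  ry.zeros(mv.G);
  for (int k = 0; k < mv.faces.nrow(); ++k) {
    int gA = mv.faces(k, 0) - 1, gB = mv.faces(k, 1) - 1;
    double mf = 0.5 * (m[gA] + m[gB]);
    double c = mv.faper[k] * h * mf;
    // Gm_A += c * n_hat (+axis from A to B), Gm_B -= c * n_hat;
    // rhs = -beta * Gm
    if (mv.faces(k, 2) == 0) {
      rx[gA] -= beta * c;
      rx[gB] += beta * c;
    } else {
      ry[gA] -= beta * c;
      ry[gB] += beta * c;
    }
  }
  if (variant == 0) { // ZV front contribution with extrapolated myosin
    for (int g = 0; g < mv.G; ++g) {
      if (!mv.gcut[g]) continue;
      rx[g] -= beta * mb[g] * mv.gNx[g];
      ry[g] -= beta * mb[g] * mv.gNy[g];
    }
  }
}

// transport matrix and rhs for one backward-Euler solve
static void transport_system(const MeshView& mv, const arma::vec& m_coef,
                             const arma::mat& u, const arma::vec& anchor_mass,
                             double dt, double mmax_u, double mmax_d,
                             double d_floor, const arma::vec& source,
                             arma::mat& A, arma::vec& rhs, int& floor_hits) {
  const int G = mv.G;
  const double h = mv.h;
  A.zeros(G, G);
  rhs = anchor_mass;
  floor_hits = 0;
  std::vector<double> dg(G), fg(G);
  for (int g = 0; g < G; ++g) {
    double d = 1.0 - m_coef[g] / mmax_d;
    if (d < d_floor) { d = d_floor; ++floor_hits; }
    dg[g] = d;
    fg[g] = adv_factor(m_coef[g], mmax_u);
    A(g, g) = mv.gvol[g];
    if (source.n_elem > 0) rhs[g] += dt * mv.gvol[g] * source[g];
  }
  for (int k = 0; k < mv.faces.nrow(); ++k) {
    int gA = mv.faces(k, 0) - 1, gB = mv.faces(k, 1) - 1;
    double ap = mv.faper[k];
    int dir = mv.faces(k, 2);
    double df = 0.5 * (dg[gA] + dg[gB]);
    double cd = dt * ap * df;
    A(gA, gA) += cd; A(gA, gB) -= cd;
    A(gB, gB) += cd; A(gB, gA) -= cd;
    double un = 0.5 * (u(gA, dir) * fg[gA] + u(gB, dir) * fg[gB]); // A -> B
    double ca = dt * ap * h;
    if (un > 0) {
      A(gA, gA) += ca * un;
      A(gB, gA) -= ca * un;
    } else {
      A(gA, gB) += ca * un;
      A(gB, gB) -= ca * un;
    }
  }
}

// boundary myosin for ZV: extrapolate m to each cut group's front midpoint
static arma::vec boundary_myosin(const MeshView& mv, const arma::vec& m) {
  std::vector<int> cuts;
  for (int g = 0; g < mv.G; ++g)
    if (mv.gcut[g]) cuts.push_back(g);
  arma::vec mb(mv.G, arma::fill::zeros);
  if (cuts.empty()) return mb;
  NumericMatrix pts((int)cuts.size(), 2), nrm((int)cuts.size(), 2);
  for (size_t k = 0; k < cuts.size(); ++k) {
    int g = cuts[k];
    double Nn = std::sqrt(mv.gNx[g] * mv.gNx[g] + mv.gNy[g] * mv.gNy[g]);
    pts((int)k, 0) = mv.gbpx[g];
    pts((int)k, 1) = mv.gbpy[g];
    nrm((int)k, 0) = Nn > 0 ? mv.gNx[g] / Nn : 1.0;
    nrm((int)k, 1) = Nn > 0 ? mv.gNy[g] / Nn : 0.0;
  }
  arma::vec vals((int)cuts.size());
  int nfb = 0;
  extrap_points_ls(mv, m, pts, vals, nfb);
  for (size_t k = 0; k < cuts.size(); ++k)
    mb[cuts[k]] = std::max(0.0, vals[(int)k]);
  return mb;
}

// [[Rcpp::export]]
List fb_solve_cpp(List mesh, NumericVector m, double alpha, double beta,
                  int variant) {
  MeshView mv(mesh);
  arma::vec mm(m.begin(), m.size());
  arma::mat A = fb_matrix(mv, alpha, variant);
  arma::vec mb = (variant == 0) ? boundary_myosin(mv, mm)
                                : arma::vec(mv.G, arma::fill::zeros);
  arma::vec rx, ry;
  fb_rhs(mv, mm, beta, variant, mb, rx, ry);
  arma::mat rhs(mv.G, 2);
  rhs.col(0) = rx;
  rhs.col(1) = ry;
  arma::mat u = arma::solve(A, rhs);
  arma::mat res = A * u - rhs;
  double maxres = res.n_elem ? arma::abs(res).max() : 0.0;
  // scale residual per unit volume (pointwise PDE residual)
  arma::vec vol(mv.G);
  for (int g = 0; g < mv.G; ++g) vol[g] = mv.gvol[g];
  arma::mat resv = res.each_col() / vol;
  double maxresv = resv.n_elem ? arma::abs(resv).max() : 0.0;
  return List::create(_["ux"] = NumericVector(u.colptr(0), u.colptr(0) + mv.G),
                      _["uy"] = NumericVector(u.colptr(1), u.colptr(1) + mv.G),
                      _["residual"] = maxres, _["residual_pointwise"] = maxresv);
}

// [[Rcpp::export]]
List transport_step_cpp(List mesh, NumericVector anchor_mass,
                        NumericVector m_coef, NumericMatrix u, double dt,
                        double mmax_u, double mmax_d, double d_floor,
                        NumericVector source) {
  MeshView mv(mesh);
  arma::vec anch(anchor_mass.begin(), anchor_mass.size());
  arma::vec mc(m_coef.begin(), m_coef.size());
  arma::mat uu(u.begin(), u.nrow(), u.ncol());
  arma::vec src;
  if (source.size() == mv.G) src = arma::vec(source.begin(), source.size());
  arma::mat A;
  arma::vec rhs;
  int fl = 0;
  transport_system(mv, mc, uu, anch, dt, mmax_u, mmax_d, d_floor, src, A, rhs,
                   fl);
  arma::vec m = arma::solve(A, rhs);
  return List::create(_["m"] = NumericVector(m.begin(), m.end()),
                      _["floor_hits"] = fl);
}

// one segregated fixed-point solve (the inner loop of a time step); the mesh
// is held fixed, the anchor is the previous time-step mass distribution
// [[Rcpp::export]]
List segregated_solve_cpp(List mesh, NumericVector anchor_mass,
                          NumericVector m_init, NumericMatrix u_init,
                          double dt, double alpha, double beta, double mmax_u,
                          double mmax_d, int variant, double fp_tol,
                          int max_iters, double d_floor) {
  MeshView mv(mesh);
  const int G = mv.G;
  arma::vec anch(anchor_mass.begin(), anchor_mass.size());
  arma::vec m_it(m_init.begin(), m_init.size());
  arma::mat u_it(u_init.begin(), u_init.nrow(), u_init.ncol());
  arma::mat Afb = fb_matrix(mv, alpha, variant);
  arma::mat L, U, P;
  if (!arma::lu(L, U, P, Afb)) stop("force-balance factorization failed");
  arma::vec src; // none
  arma::mat At;
  arma::vec rhs_t;
  int iters = 0, floor_hits = 0;
  double err_u = NA_REAL, err_m = NA_REAL;
  bool converged = false;
  arma::mat u_new;
  arma::vec m_new;
  for (int n = 1; n <= max_iters; ++n) {
    iters = n;
    arma::vec mb = (variant == 0) ? boundary_myosin(mv, m_it)
                                  : arma::vec(G, arma::fill::zeros);
    arma::vec rx, ry;
    fb_rhs(mv, m_it, beta, variant, mb, rx, ry);
    arma::mat rhs(G, 2);
    rhs.col(0) = rx;
    rhs.col(1) = ry;
    arma::mat y = arma::solve(arma::trimatl(L), P * rhs);
    u_new = arma::solve(arma::trimatu(U), y);
    int fl = 0;
    transport_system(mv, m_it, u_new, anch, dt, mmax_u, mmax_d, d_floor, src,
                     At, rhs_t, fl);
    floor_hits += fl;
    m_new = arma::solve(At, rhs_t);
    err_u = arma::abs(u_new - u_it).max();
    err_m = arma::abs(m_new - m_it).max();
    if (err_u <= fp_tol && err_m <= fp_tol) {
      converged = true;
      break;
    }
    m_it = m_new;
    u_it = u_new;
  }
  NumericMatrix uo(G, 2);
  for (int g = 0; g < G; ++g) {
    uo(g, 0) = u_new(g, 0);
    uo(g, 1) = u_new(g, 1);
  }
  return List::create(_["m"] = NumericVector(m_new.begin(), m_new.end()),
                      _["u"] = uo, _["iters"] = iters,
                      _["converged"] = converged, _["err_u"] = err_u,
                      _["err_m"] = err_m, _["floor_hits"] = floor_hits);
}

// residuals of the fully coupled one-step system at (m, u): force balance
// with myosin m, and backward-Euler transport with coefficients from m itself
// [[Rcpp::export]]
List coupled_residual_cpp(List mesh, NumericVector anchor_mass,
                          NumericVector m, NumericMatrix u, double dt,
                          double alpha, double beta, double mmax_u,
                          double mmax_d, int variant, double d_floor) {
  MeshView mv(mesh);
  arma::vec mm(m.begin(), m.size());
  arma::mat uu(u.begin(), u.nrow(), u.ncol());
  arma::vec anch(anchor_mass.begin(), anchor_mass.size());
  arma::mat Afb = fb_matrix(mv, alpha, variant);
  arma::vec mb = (variant == 0) ? boundary_myosin(mv, mm)
                                : arma::vec(mv.G, arma::fill::zeros);
  arma::vec rx, ry;
  fb_rhs(mv, mm, beta, variant, mb, rx, ry);
  arma::mat rhs(mv.G, 2);
  rhs.col(0) = rx;
  rhs.col(1) = ry;
  arma::mat rfb = Afb * uu - rhs;
  arma::mat At;
  arma::vec rhs_t, src;
  int fl = 0;
  transport_system(mv, mm, uu, anch, dt, mmax_u, mmax_d, d_floor, src, At,
                   rhs_t, fl);
  arma::vec rtr = At * mm - rhs_t;
  return List::create(_["res_u"] = arma::abs(rfb).max(),
                      _["res_m"] = arma::abs(rtr).max());
}

// fixed-matrix diffusion benchmark: backward Euler with separable source
// S(x, t) = exp(-decay * t) * s(x); matrix factored once
// [[Rcpp::export]]
NumericVector bench_diffusion_cpp(List mesh, NumericVector m0,
                                  NumericVector svec, double decay, double dt,
                                  int nsteps) {
  MeshView mv(mesh);
  const int G = mv.G;
  arma::mat A(G, G, arma::fill::zeros);
  for (int g = 0; g < G; ++g) A(g, g) = mv.gvol[g];
  for (int k = 0; k < mv.faces.nrow(); ++k) {
    int gA = mv.faces(k, 0) - 1, gB = mv.faces(k, 1) - 1;
    double cd = dt * mv.faper[k];
    A(gA, gA) += cd; A(gA, gB) -= cd;
    A(gB, gB) += cd; A(gB, gA) -= cd;
  }
  arma::mat L, U, P;
  if (!arma::lu(L, U, P, A)) stop("benchmark factorization failed");
  arma::vec m(m0.begin(), m0.size());
  arma::vec s(svec.begin(), svec.size());
  arma::vec vol(G);
  for (int g = 0; g < G; ++g) vol[g] = mv.gvol[g];
  double t = 0.0;
  for (int k = 0; k < nsteps; ++k) {
    t += dt;
    arma::vec rhs = vol % m + dt * std::exp(-decay * t) * (vol % s);
    arma::vec y = arma::solve(arma::trimatl(L), P * rhs);
    m = arma::solve(arma::trimatu(U), y);
  }
  return NumericVector(m.begin(), m.end());
}
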