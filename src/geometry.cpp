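#include <Rcpp.h>
using namespace Rcpp;

// Planar polygon kernel used by range construction and rasterization.
// Polygons are open rings: an n x 2 matrix of vertices, counterclockwise.

static double ring_area(const std::vector<double>& x,
                        const std::vector<double>& y) {
  const int n = x.size();
  if (n < 3) return 0.0;
  double a = 0.0;
  for (int i = 0, j = n - 1; i < n; j = i++)
    a += x[j] * y[i] - x[i] * y[j];
  return 0.5 * a;
}

// [[Rcpp::export]]
double poly_area_cpp(NumericMatrix poly) {
  const int n = poly.nrow();
  if (n < 3) return 0.0;
  double a = 0.0;
  for (int i = 0, j = n - 1; i < n; j = i++)
    a += poly(j, 0) * poly(i, 1) - poly(i, 0) * poly(j, 1);
  return 0.5 * a;
}

// Clip a subject ring against one half-plane: keep points on the left of
// (or on) the directed line a -> b. Sutherland-Hodgman step.
static void clip_halfplane(std::vector<double>& x, std::vector<double>& y,
                           double ax, double ay, double bx, double by) {
  const int n = x.size();
  std::vector<double> ox, oy;
  ox.reserve(n + 4);
  oy.reserve(n + 4);
  const double ex = bx - ax, ey = by - ay;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    const double sj = ex * (y[j] - ay) - ey * (x[j] - ax); // >0 inside
    const double si = ex * (y[i] - ay) - ey * (x[i] - ax);
    const bool inj = sj >= -1e-12, ini = si >= -1e-12;
    if (inj != ini) {
      const double t = sj / (sj - si);
      ox.push_back(x[j] + t * (x[i] - x[j]));
      oy.push_back(y[j] + t * (y[i] - y[j]));
    }
    if (ini) {
      ox.push_back(x[i]);
      oy.push_back(y[i]);
    }
  }
  x.swap(ox);
  y.swap(oy);
}

// [[Rcpp::export]]
NumericMatrix clip_convex_cpp(NumericMatrix subject, NumericMatrix clip) {
  const int ns = subject.nrow(), nc = clip.nrow();
  std::vector<double> x(ns), y(ns);
  for (int i = 0; i < ns; ++i) {
    x[i] = subject(i, 0);
    y[i] = subject(i, 1);
  }
  for (int i = 0, j = nc - 1; i < nc; j = i++) {
    if (x.empty()) break;
    clip_halfplane(x, y, clip(j, 0), clip(j, 1), clip(i, 0), clip(i, 1));
  }
  const int n = x.size();
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = x[i];
    out(i, 1) = y[i];
  }
  return out;
}

static double clip_area_rect(const NumericMatrix& poly, double x0, double x1,
                             double y0, double y1) {
  const int n = poly.nrow();
  std::vector<double> x(n), y(n);
  for (int i = 0; i < n; ++i) {
    x[i] = poly(i, 0);
    y[i] = poly(i, 1);
  }
  clip_halfplane(x, y, x0, y0, x1, y0); // bottom
  if (!x.empty()) clip_halfplane(x, y, x1, y0, x1, y1); // right
  if (!x.empty()) clip_halfplane(x, y, x1, y1, x0, y1); // top
  if (!x.empty()) clip_halfplane(x, y, x0, y1, x0, y0); // left
  return ring_area(x, y);
}

// Area of (union of disjoint convex pieces) inside each cell of a regular
// grid with breaks xb (length nx+1) and yb (length ny+1). Returns nx x ny.
// [[Rcpp::export]]
NumericMatrix mosaic_grid_cover_cpp(List pieces, NumericVector xb,
                                    NumericVector yb) {
  const int nx = xb.size() - 1, ny = yb.size() - 1;
  NumericMatrix out(nx, ny);
  for (int p = 0; p < pieces.size(); ++p) {
    NumericMatrix poly = pieces[p];
    const int n = poly.nrow();
    if (n < 3) continue;
    double bx0 = poly(0, 0), bx1 = bx0, by0 = poly(0, 1), by1 = by0;
    for (int i = 1; i < n; ++i) {
      bx0 = std::min(bx0, poly(i, 0));
      bx1 = std::max(bx1, poly(i, 0));
      by0 = std::min(by0, poly(i, 1));
      by1 = std::max(by1, poly(i, 1));
    }
    for (int ix = 0; ix < nx; ++ix) {
      if (xb[ix + 1] <= bx0 || xb[ix] >= bx1) continue;
      for (int iy = 0; iy < ny; ++iy) {
        if (yb[iy + 1] <= by0 || yb[iy] >= by1) continue;
        out(ix, iy) += clip_area_rect(poly, xb[ix], xb[ix + 1], yb[iy],
                                      yb[iy + 1]);
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
double mosaic_area_cpp(List pieces) {
  double a = 0.0;
  for (int p = 0; p < pieces.size(); ++p) {
    NumericMatrix poly = pieces[p];
    a += poly_area_cpp(poly);
  }
  return a;
}
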