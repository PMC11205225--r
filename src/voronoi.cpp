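#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Bounded Voronoi tessellation of a 2-D point set by certified half-plane
// clipping.  Each cell starts as a large bounding box and is clipped against
// the perpendicular bisectors of neighbours in order of increasing distance.
// A cell is final once every unprocessed neighbour q satisfies
// d(p, q) >= 2 * max_vertex_distance(cell): such a q cannot cut the cell.

namespace {

struct Pt { double x, y; };

// Sutherland-Hodgman clip of polygon `poly` against half-plane
// {x : n . x <= c}; returns clipped polygon.
std::vector<Pt> clip_halfplane(const std::vector<Pt>& poly,
                               double nx, double ny, double c) {
  std::vector<Pt> out;
  const int n = (int)poly.size();
  if (n == 0) return out;
  out.reserve(n + 2);
  for (int i = 0; i < n; ++i) {
    const Pt& a = poly[i];
    const Pt& b = poly[(i + 1) % n];
    const double da = nx * a.x + ny * a.y - c;
    const double db = nx * b.x + ny * b.y - c;
    const bool ina = da <= 0.0, inb = db <= 0.0;
    if (ina) {
      out.push_back(a);
      if (!inb) {
        const double t = da / (da - db);
        out.push_back({a.x + t * (b.x - a.x), a.y + t * (b.y - a.y)});
      }
    } else if (inb) {
      const double t = da / (da - db);
      out.push_back({a.x + t * (b.x - a.x), a.y + t * (b.y - a.y)});
    }
  }
  return out;
}

double max_sq_dist(const std::vector<Pt>& poly, double px, double py) {
  double m = 0.0;
  for (const Pt& v : poly) {
    const double dx = v.x - px, dy = v.y - py;
    const double d2 = dx * dx + dy * dy;
    if (d2 > m) m = d2;
  }
  return m;
}

double shoelace_area(const std::vector<Pt>& poly) {
  const int n = (int)poly.size();
  double a = 0.0;
  for (int i = 0; i < n; ++i) {
    const Pt& p = poly[i];
    const Pt& q = poly[(i + 1) % n];
    a += p.x * q.y - q.x * p.y;
  }
  return std::fabs(a) / 2.0;
}

// simple uniform grid for neighbour queries
struct BinGrid {
  double x0, y0, cs;
  int nx, ny;
  std::vector<std::vector<int>> bins;

  BinGrid(const NumericVector& x, const NumericVector& y,
          double xmin, double ymin, double xmax, double ymax, double cell) {
    cs = cell;
    x0 = xmin; y0 = ymin;
    nx = std::max(1, (int)std::ceil((xmax - xmin) / cs));
    ny = std::max(1, (int)std::ceil((ymax - ymin) / cs));
    bins.assign((size_t)nx * ny, {});
    for (int i = 0; i < x.size(); ++i) {
      int ix = std::min(nx - 1, std::max(0, (int)((x[i] - x0) / cs)));
      int iy = std::min(ny - 1, std::max(0, (int)((y[i] - y0) / cs)));
      bins[(size_t)iy * nx + ix].push_back(i);
    }
  }

  // indices of points within Chebyshev radius r of (qx, qy)
  void gather(double qx, double qy, double r, std::vector<int>& out) const {
    out.clear();
    int ix0 = std::max(0, (int)std::floor((qx - r - x0) / cs));
    int ix1 = std::min(nx - 1, (int)std::floor((qx + r - x0) / cs));
    int iy0 = std::max(0, (int)std::floor((qy - r - y0) / cs));
    int iy1 = std::min(ny - 1, (int)std::floor((qy + r - y0) / cs));
    for (int iy = iy0; iy <= iy1; ++iy)
      for (int ix = ix0; ix <= ix1; ++ix)
        for (int j : bins[(size_t)iy * nx + ix]) out.push_back(j);
  }
};

} // namespace

// [[Rcpp::export(name = ".cpp_voronoi")]]
List cpp_voronoi(NumericVector x, NumericVector y,
                 double roi_w, double roi_h) {
  const int n = x.size();
  const double B = std::max(roi_w, roi_h);      // halo around the ROI
  const double spacing = std::sqrt(roi_w * roi_h / std::max(1, n));
  BinGrid grid(x, y, 0.0, 0.0, roi_w, roi_h, std::max(spacing, 1e-6) * 2.0);

  List polys(n);
  NumericVector area(n);
  LogicalVector bounded(n);
  NumericMatrix bbox(n, 4);   // xmin, ymin, xmax, ymax of cell vertices
  const double eps = 1e-9 * B;

  std::vector<int> cand;
  std::vector<std::pair<double, int>> byd;

  for (int i = 0; i < n; ++i) {
    const double px = x[i], py = y[i];
    std::vector<Pt> poly = {{-B, -B}, {roi_w + B, -B},
                            {roi_w + B, roi_h + B}, {-B, roi_h + B}};
    double r = 3.0 * spacing;
    byd.clear();
    bool all_in = false;

    for (;;) {
      grid.gather(px, py, r, cand);
      byd.clear();
      byd.reserve(cand.size());
      for (int j : cand) {
        if (j == i) continue;
        const double dx = x[j] - px, dy = y[j] - py;
        byd.push_back({dx * dx + dy * dy, j});
      }
      std::sort(byd.begin(), byd.end());
      all_in = ((int)byd.size() == n - 1);

      // re-clip from scratch each round; clipping is idempotent and the
      // sorted early-exit makes repeat rounds nearly free
      double rv2 = max_sq_dist(poly, px, py);
      for (int t = 0; t < (int)byd.size(); ++t) {
        const double d2 = byd[t].first;
        if (d2 >= 4.0 * rv2) break;   // sorted: no further point can cut
        const int j = byd[t].second;
        const double nx_ = x[j] - px, ny_ = y[j] - py;
        const double c = nx_ * (px + x[j]) / 2.0 + ny_ * (py + y[j]) / 2.0;
        std::vector<Pt> cut = clip_halfplane(poly, nx_, ny_, c);
        if (!cut.empty()) poly = std::move(cut);
        rv2 = max_sq_dist(poly, px, py);
      }

      const double rv = std::sqrt(rv2);
      if (all_in || 2.0 * rv <= r) break;
      r = std::max(2.0 * r, 2.0 * rv + spacing);
      if (r > 4.0 * B + 2.0 * spacing) r = 4.0 * B + 2.0 * spacing; // covers all
    }

    const int m = (int)poly.size();
    NumericMatrix vm(m, 2);
    double xmn = R_PosInf, ymn = R_PosInf, xmx = R_NegInf, ymx = R_NegInf;
    bool inside = true;
    for (int v = 0; v < m; ++v) {
      vm(v, 0) = poly[v].x;
      vm(v, 1) = poly[v].y;
      xmn = std::min(xmn, poly[v].x); xmx = std::max(xmx, poly[v].x);
      ymn = std::min(ymn, poly[v].y); ymx = std::max(ymx, poly[v].y);
      if (poly[v].x < -eps || poly[v].x > roi_w + eps ||
          poly[v].y < -eps || poly[v].y > roi_h + eps) inside = false;
    }
    polys[i] = vm;
    area[i] = shoelace_area(poly);
    bounded[i] = inside && m >= 3;
    bbox(i, 0) = xmn; bbox(i, 1) = ymn; bbox(i, 2) = xmx; bbox(i, 3) = ymx;
  }

  return List::create(_["polygons"] = polys, _["area"] = area,
                      _["bounded"] = bounded, _["bbox"] = bbox);
}

// Adaptive-window density engine.
//
// For each query point the smallest axis-aligned square window (side grown in
// whole-pixel increments of `px_um`) whose interior strictly contains the
// Voronoi cells of at least `k` cones is found.  The per-cone quantity
//   h_i = max(qx - xmin_i, xmax_i - qx, qy - ymin_i, ymax_i - qy)
// is the half-side a window centred at q needs before cell i fits; the k-th
// smallest h determines the window.  Density is the bounded-Voronoi ratio:
// (number of contained cells) / (summed area of those cells).
//
// [[Rcpp::export(name = ".cpp_density_at")]]
List cpp_density_at(NumericMatrix bbox, NumericVector cx, NumericVector cy,
                    NumericVector cell_area,
                    NumericVector qx, NumericVector qy,
                    int k, double px_um, double roi_w, double roi_h) {
  const int n = bbox.nrow();
  const int nq = qx.size();
  NumericVector dens(nq, NA_REAL), wside(nq, NA_REAL);
  IntegerVector count(nq, NA_INTEGER);
  if (n < k || k < 1) {
    return List::create(_["density"] = dens, _["window_side"] = wside,
                        _["count"] = count);
  }

  // half-extent of each cell's bbox around its cone, and the global max
  double r_half_max = 0.0;
  for (int i = 0; i < n; ++i) {
    const double rh = std::max(
        std::max(cx[i] - bbox(i, 0), bbox(i, 2) - cx[i]),
        std::max(cy[i] - bbox(i, 1), bbox(i, 3) - cy[i]));
    r_half_max = std::max(r_half_max, rh);
  }

  const double spacing = std::sqrt(roi_w * roi_h / n);
  BinGrid grid(cx, cy, 0.0, 0.0, roi_w, roi_h, std::max(spacing, 1e-6) * 3.0);
  const double Rall = std::max(roi_w, roi_h) + r_half_max + 1.0;

  std::vector<int> cand;
  std::vector<double> hs;

  for (int q = 0; q < nq; ++q) {
    const double X = qx[q], Y = qy[q];
    double R = 0.7 * std::sqrt((double)k) * spacing + r_half_max + px_um;
    double half = NA_REAL;
    for (;;) {
      grid.gather(X, Y, R, cand);
      if ((int)cand.size() < k && R < Rall) { R = std::min(2.0 * R, Rall); continue; }
      if ((int)cand.size() < k) break;   // fewer than k cells in total
      hs.clear();
      hs.reserve(cand.size());
      for (int j : cand) {
        const double h = std::max(
            std::max(X - bbox(j, 0), bbox(j, 2) - X),
            std::max(Y - bbox(j, 1), bbox(j, 3) - Y));
        hs.push_back(h);
      }
      std::nth_element(hs.begin(), hs.begin() + (k - 1), hs.end());
      const double H = hs[k - 1];
      // smallest whole-pixel side whose half strictly exceeds H
      const long Lpx = (long)std::floor(2.0 * H / px_um) + 1L;
      half = (double)Lpx * px_um / 2.0;
      // certify: every cell with h < half must have been gathered
      if (R - r_half_max >= half || R >= Rall) break;
      R = std::min(std::max(2.0 * R, half + r_half_max + px_um), Rall);
    }
    if (!R_finite(half)) continue;
    // window must fit inside the ROI
    if (X - half < -1e-9 || X + half > roi_w + 1e-9 ||
        Y - half < -1e-9 || Y + half > roi_h + 1e-9) continue;
    int cnt = 0;
    double asum = 0.0;
    for (int j : cand) {
      const double h = std::max(
          std::max(X - bbox(j, 0), bbox(j, 2) - X),
          std::max(Y - bbox(j, 1), bbox(j, 3) - Y));
      if (h < half) { ++cnt; asum += cell_area[j]; }
    }
    if (cnt < k || asum <= 0.0) continue;  // cannot happen if certified
    dens[q] = (double)cnt / asum * 1e6;    // um^-2 -> mm^-2
    wside[q] = 2.0 * half;
    count[q] = cnt;
  }

  return List::create(_["density"] = dens, _["window_side"] = wside,
                      _["count"] = count);
}
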