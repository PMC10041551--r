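// Exact slab-decomposition measures for unions of convex polygons.
//
// Between consecutive critical x-coordinates (edge endpoints and edge
// crossings) every covered-interval endpoint is linear in x, so the
// covered length L(x) is piecewise linear and x*L(x), y-moment terms are
// piecewise quadratic; 2-point Gauss-Legendre per slab integrates them
// exactly up to floating point.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

struct Edge {
  double x1, y1, x2, y2;
  int hull;   // hull id (0-based), offset so A and B sets never collide
  bool setB;
};

// y-interval per hull cut by the vertical at x, for edges in [lo, hi) of
// the active list; results appended to out as (ylo, yhi) pairs.
static void hull_intervals(const std::vector<Edge>& edges,
                           const std::vector<int>& active, double x,
                           bool wantB, int nhull,
                           std::vector<double>& minY,
                           std::vector<double>& maxY,
                           std::vector<int>& touched,
                           std::vector<std::pair<double, double> >& out) {
  touched.clear();
  for (size_t k = 0; k < active.size(); ++k) {
    const Edge& e = edges[active[k]];
    if (e.setB != wantB) continue;
    double lo = std::min(e.x1, e.x2), hi = std::max(e.x1, e.x2);
    if (x < lo || x > hi || e.x1 == e.x2) continue;
    double y = e.y1 + (x - e.x1) * (e.y2 - e.y1) / (e.x2 - e.x1);
    if (minY[e.hull] > maxY[e.hull]) touched.push_back(e.hull);
    if (y < minY[e.hull]) minY[e.hull] = y;
    if (y > maxY[e.hull]) maxY[e.hull] = y;
  }
  out.clear();
  for (size_t k = 0; k < touched.size(); ++k) {
    int h = touched[k];
    if (maxY[h] > minY[h]) out.push_back(std::make_pair(minY[h], maxY[h]));
    minY[h] = 1e300;
    maxY[h] = -1e300;
  }
  std::sort(out.begin(), out.end());
}

static void merge_intervals(std::vector<std::pair<double, double> >& iv) {
  if (iv.empty()) return;
  size_t w = 0;
  for (size_t i = 1; i < iv.size(); ++i) {
    if (iv[i].first <= iv[w].second) {
      if (iv[i].second > iv[w].second) iv[w].second = iv[i].second;
    } else {
      iv[++w] = iv[i];
    }
  }
  iv.resize(w + 1);
}

static void intersect_intervals(
    const std::vector<std::pair<double, double> >& a,
    const std::vector<std::pair<double, double> >& b,
    std::vector<std::pair<double, double> >& out) {
  out.clear();
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    double lo = std::max(a[i].first, b[j].first);
    double hi = std::min(a[i].second, b[j].second);
    if (hi > lo) out.push_back(std::make_pair(lo, hi));
    if (a[i].second < b[j].second) ++i; else ++j;
  }
}

// edges matrices: columns x1 y1 x2 y2 hull_id (1-based)
// mode 0: union measures of A (area, mx, my); mode 1: area of
// union(A) x union(B) intersection (mx, my zero).
static NumericVector slab_core(const NumericMatrix& edA,
                               const NumericMatrix& edB, int mode) {
  std::vector<Edge> edges;
  int nhullA = 0, nhullB = 0;
  for (int i = 0; i < edA.nrow(); ++i) {
    nhullA = std::max(nhullA, (int)edA(i, 4));
  }
  for (int i = 0; i < edA.nrow(); ++i) {
    Edge e = {edA(i, 0), edA(i, 1), edA(i, 2), edA(i, 3),
              (int)edA(i, 4) - 1, false};
    edges.push_back(e);
  }
  if (mode == 1) {
    for (int i = 0; i < edB.nrow(); ++i) {
      nhullB = std::max(nhullB, (int)edB(i, 4));
    }
    for (int i = 0; i < edB.nrow(); ++i) {
      Edge e = {edB(i, 0), edB(i, 1), edB(i, 2), edB(i, 3),
                nhullA + (int)edB(i, 4) - 1, true};
      edges.push_back(e);
    }
  }
  size_t ne = edges.size();
  NumericVector res(3);
  if (ne == 0) return res;

  // critical xs: endpoints + pairwise crossings (bbox-filtered)
  std::vector<double> xs;
  xs.reserve(ne * 2);
  for (size_t i = 0; i < ne; ++i) {
    xs.push_back(edges[i].x1);
    xs.push_back(edges[i].x2);
  }
  std::vector<size_t> byxmin(ne);
  for (size_t i = 0; i < ne; ++i) byxmin[i] = i;
  std::sort(byxmin.begin(), byxmin.end(), [&](size_t a, size_t b) {
    return std::min(edges[a].x1, edges[a].x2) <
           std::min(edges[b].x1, edges[b].x2);
  });
  for (size_t ii = 0; ii < ne; ++ii) {
    const Edge& e1 = edges[byxmin[ii]];
    double e1xmax = std::max(e1.x1, e1.x2);
    double px = e1.x1, py = e1.y1, rx = e1.x2 - e1.x1, ry = e1.y2 - e1.y1;
    for (size_t jj = ii + 1; jj < ne; ++jj) {
      const Edge& e2 = edges[byxmin[jj]];
      if (std::min(e2.x1, e2.x2) > e1xmax) break;   // sorted: no overlap left
      double qx = e2.x1, qy = e2.y1, sx = e2.x2 - e2.x1, sy = e2.y2 - e2.y1;
      double den = rx * sy - ry * sx;
      if (std::fabs(den) < 1e-14) continue;
      double t = ((qx - px) * sy - (qy - py) * sx) / den;
      double u = ((qx - px) * ry - (qy - py) * rx) / den;
      if (t >= 0 && t <= 1 && u >= 0 && u <= 1) xs.push_back(px + t * rx);
    }
  }
  std::sort(xs.begin(), xs.end());
  xs.erase(std::unique(xs.begin(), xs.end()), xs.end());

  int nhull = nhullA + nhullB;
  std::vector<double> minY(nhull, 1e300), maxY(nhull, -1e300);
  std::vector<int> touched;
  std::vector<std::pair<double, double> > ivA, ivB, ivI;
  std::vector<int> active;
  size_t nextEdge = 0;
  const double g = 0.5 / std::sqrt(3.0);
  double area = 0, mx = 0, my = 0;

  for (size_t s = 0; s + 1 < xs.size(); ++s) {
    double xl = xs[s], xr = xs[s + 1], w = xr - xl;
    if (w <= 1e-12) continue;
    // admit edges whose span reaches this slab; retire finished ones
    while (nextEdge < ne &&
           std::min(edges[byxmin[nextEdge]].x1,
                    edges[byxmin[nextEdge]].x2) <= xl) {
      active.push_back((int)byxmin[nextEdge]);
      ++nextEdge;
    }
    size_t wpos = 0;
    for (size_t k = 0; k < active.size(); ++k) {
      if (std::max(edges[active[k]].x1, edges[active[k]].x2) >= xr) {
        active[wpos++] = active[k];
      }
    }
    active.resize(wpos);
    if (active.empty()) continue;
    double mid = (xl + xr) / 2;
    double nodes[2] = {mid - g * w, mid + g * w};
    for (int q = 0; q < 2; ++q) {
      double x = nodes[q];
      hull_intervals(edges, active, x, false, nhull, minY, maxY, touched,
                     ivA);
      merge_intervals(ivA);
      const std::vector<std::pair<double, double> >* iv = &ivA;
      if (mode == 1) {
        hull_intervals(edges, active, x, true, nhull, minY, maxY, touched,
                       ivB);
        merge_intervals(ivB);
        intersect_intervals(ivA, ivB, ivI);
        iv = &ivI;
      }
      double L = 0, S = 0;
      for (size_t k = 0; k < iv->size(); ++k) {
        L += (*iv)[k].second - (*iv)[k].first;
        S += ((*iv)[k].second * (*iv)[k].second -
              (*iv)[k].first * (*iv)[k].first) / 2;
      }
      area += w / 2 * L;
      mx += w / 2 * x * L;
      my += w / 2 * S;
    }
  }
  res[0] = area;
  res[1] = mx;
  res[2] = my;
  return res;
}

// [[Rcpp::export]]
NumericVector cpp_union_measures(NumericMatrix edges) {
  return slab_core(edges, NumericMatrix(0, 5), 0);
}

// [[Rcpp::export]]
double cpp_intersection_area(NumericMatrix edges_a, NumericMatrix edges_b) {
  return slab_core(edges_a, edges_b, 1)[0];
}
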