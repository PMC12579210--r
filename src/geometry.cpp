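#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Planar proximity graphs from the empty-circle principle.
//
// Circles through a point pair (i, j) are parameterized by the signed offset
// s of their center along the perpendicular bisector of ij. A third point k
// lies strictly inside the circle at offset s iff  b_k - a_k * s < 0  with
//   a_k = 2 * u . (k - m),   b_k = |m - k|^2 - |m - i|^2,
// where m is the midpoint and u the unit bisector direction. Each blocker
// therefore forbids a half-line in s, and an empty circle exists iff the
// union of forbidden half-lines leaves a gap. This gives exact Delaunay
// edge tests (any s) and alpha-shape edge tests (s = +-s_alpha) without a
// triangulation library, and stays well-conditioned for tiny alpha because
// no squared radii are ever subtracted.

struct Pt { double x, y; };

static inline void pair_frame(const Pt &pi, const Pt &pj, Pt &m, Pt &u) {
  m.x = 0.5 * (pi.x + pj.x); m.y = 0.5 * (pi.y + pj.y);
  double ex = pj.x - pi.x, ey = pj.y - pi.y;
  double len = std::sqrt(ex * ex + ey * ey);
  u.x = -ey / len; u.y = ex / len;
}

// Delaunay edges restricted to k-nearest-neighbor candidate pairs.
// Returns a 2-column 1-based edge matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_delaunay_edges(NumericMatrix X, IntegerMatrix knn) {
  const int n = X.nrow(), k = knn.ncol();
  std::vector<Pt> P(n);
  for (int i = 0; i < n; ++i) { P[i].x = X(i, 0); P[i].y = X(i, 1); }

  std::vector<std::pair<int, int>> edges;
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < k; ++c) {
      int j = knn(i, c) - 1;
      if (j <= i) continue;  // each unordered pair once
      Pt m, u;
      pair_frame(P[i], P[j], m, u);
      double mi2 = (m.x - P[i].x) * (m.x - P[i].x) + (m.y - P[i].y) * (m.y - P[i].y);
      double lo = -HUGE_VAL, hi = HUGE_VAL;
      bool dead = false;
      for (int q = 0; q < n && !dead; ++q) {
        if (q == i || q == j) continue;
        double bx = m.x - P[q].x, by = m.y - P[q].y;
        double b = bx * bx + by * by - mi2;
        double a = 2.0 * (u.x * (P[q].x - m.x) + u.y * (P[q].y - m.y));
        if (std::fabs(a) < 1e-14) {
          if (b < -1e-14) dead = true;  // blocked for every s
        } else if (a > 0) {
          hi = std::min(hi, b / a);
        } else {
          lo = std::max(lo, b / a);
        }
        if (lo >= hi + 1e-14) dead = true;
      }
      if (!dead && lo < hi + 1e-14) edges.push_back(std::make_pair(i, j));
    }
  }

  // Degenerate (cocircular) configurations can admit both diagonals of a
  // quad; drop the longer of any two crossing edges (ties: later pair).
  auto cross2 = [](double ox, double oy, double ax, double ay, double bx, double by) {
    return (ax - ox) * (by - oy) - (ay - oy) * (bx - ox);
  };
  std::vector<bool> keep(edges.size(), true);
  for (size_t e1 = 0; e1 < edges.size(); ++e1) {
    if (!keep[e1]) continue;
    for (size_t e2 = e1 + 1; e2 < edges.size(); ++e2) {
      if (!keep[e2]) continue;
      int a = edges[e1].first, b = edges[e1].second;
      int c = edges[e2].first, d = edges[e2].second;
      if (a == c || a == d || b == c || b == d) continue;
      double d1 = cross2(P[a].x, P[a].y, P[b].x, P[b].y, P[c].x, P[c].y);
      double d2 = cross2(P[a].x, P[a].y, P[b].x, P[b].y, P[d].x, P[d].y);
      double d3 = cross2(P[c].x, P[c].y, P[d].x, P[d].y, P[a].x, P[a].y);
      double d4 = cross2(P[c].x, P[c].y, P[d].x, P[d].y, P[b].x, P[b].y);
      if (d1 * d2 < 0 && d3 * d4 < 0) {
        double l1 = std::hypot(P[a].x - P[b].x, P[a].y - P[b].y);
        double l2 = std::hypot(P[c].x - P[d].x, P[c].y - P[d].y);
        if (l1 > l2 + 1e-12) { keep[e1] = false; break; }
        else keep[e2] = false;
      }
    }
  }

  int ne = 0;
  for (size_t e = 0; e < edges.size(); ++e) if (keep[e]) ++ne;
  IntegerMatrix out(ne, 2);
  int r = 0;
  for (size_t e = 0; e < edges.size(); ++e) {
    if (!keep[e]) continue;
    out(r, 0) = edges[e].first + 1;
    out(r, 1) = edges[e].second + 1;
    ++r;
  }
  return out;
}

// Alpha-shape boundary edges: pair (i, j) is alpha-exposed iff one of the
// two circles of radius 1/alpha through i and j (centers at s = +-s_alpha)
// contains no other point strictly inside.
// [[Rcpp::export]]
IntegerMatrix cpp_alpha_edges(NumericMatrix X, double alpha) {
  const int n = X.nrow();
  const double ralpha = 1.0 / alpha;
  std::vector<Pt> P(n);
  for (int i = 0; i < n; ++i) { P[i].x = X(i, 0); P[i].y = X(i, 1); }
  std::vector<std::pair<int, int>> edges;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = P[j].x - P[i].x, dy = P[j].y - P[i].y;
      double d2 = dx * dx + dy * dy;
      if (d2 > 4.0 * ralpha * ralpha) continue;
      Pt m, u;
      pair_frame(P[i], P[j], m, u);
      double s_alpha = std::sqrt(std::max(0.0, ralpha * ralpha - 0.25 * d2));
      double mi2 = 0.25 * d2;
      bool plus_ok = true, minus_ok = true;
      for (int q = 0; q < n && (plus_ok || minus_ok); ++q) {
        if (q == i || q == j) continue;
        double bx = m.x - P[q].x, by = m.y - P[q].y;
        double b = bx * bx + by * by - mi2;
        double a = 2.0 * (u.x * (P[q].x - m.x) + u.y * (P[q].y - m.y));
        double tol = 1e-9 * (std::fabs(b) + std::fabs(a) * s_alpha + 1e-30);
        if (plus_ok && b - a * s_alpha < -tol) plus_ok = false;
        if (minus_ok && b + a * s_alpha < -tol) minus_ok = false;
      }
      if (plus_ok || minus_ok) edges.push_back(std::make_pair(i, j));
    }
  }
  IntegerMatrix out((int)edges.size(), 2);
  for (size_t e = 0; e < edges.size(); ++e) {
    out((int)e, 0) = edges[e].first + 1;
    out((int)e, 1) = edges[e].second + 1;
  }
  return out;
}
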