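#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Exact k-nearest-neighbor indices by brute force, self excluded.
// Ties at equal distance are broken by row index (stable, documented):
// callers pass rows ordered by node id so ties resolve in id order.
// Returns 1-based index matrix n x k.
// [[Rcpp::export]]
IntegerMatrix cpp_knn(NumericMatrix X, int k) {
  const int n = X.nrow(), d = X.ncol();
  if (k >= n) stop("k must be < number of rows");
  // row-major copy for cache locality
  std::vector<double> P((size_t)n * d);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < d; ++j) P[(size_t)i * d + j] = X(i, j);

  IntegerMatrix out(n, k);
  std::vector<std::pair<double, int>> cand(n - 1);
  for (int i = 0; i < n; ++i) {
    const double *pi = &P[(size_t)i * d];
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double *pj = &P[(size_t)j * d];
      double s = 0.0;
      for (int c = 0; c < d; ++c) { double t = pi[c] - pj[c]; s += t * t; }
      cand[m++] = std::make_pair(s, j);
    }
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int c = 0; c < k; ++c) out(i, c) = cand[c].second + 1;
  }
  return out;
}

// Histogram of all pairwise distances without materializing them.
// breaks must be sorted ascending; distances outside the range are dropped.
// [[Rcpp::export]]
NumericVector cpp_pair_dist_hist(NumericMatrix X, NumericVector breaks) {
  const int n = X.nrow();
  const int nb = breaks.size() - 1;
  std::vector<double> counts(nb, 0.0);
  std::vector<double> br(breaks.begin(), breaks.end());
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = X(i, 0) - X(j, 0), dy = X(i, 1) - X(j, 1);
      double dist = std::sqrt(dx * dx + dy * dy);
      if (dist < br[0] || dist > br[nb]) continue;
      int b = (int)(std::upper_bound(br.begin(), br.end(), dist) - br.begin()) - 1;
      if (b == nb) b = nb - 1;  // right edge closed
      counts[b] += 1.0;
    }
  }
  return NumericVector(counts.begin(), counts.end());
}
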