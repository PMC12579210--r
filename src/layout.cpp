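#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Stochastic-gradient neighbor-embedding layout (UMAP-family curve
// 1/(1 + a d^(2b))) over a weighted kNN graph. Edges are sampled with
// frequency proportional to their membership weight, with `negative`
// uniform repulsive samples per positive update. `init` provides the
// starting coordinates (PCA of the high-dimensional vectors upstream).
// [[Rcpp::export]]
NumericMatrix cpp_layout(IntegerVector ei, IntegerVector ej, NumericVector ew,
                         NumericMatrix init, int n_epochs, int negative,
                         double a, double b, double lr0, double seed) {
  const int n = init.nrow();
  const R_xlen_t ne = ei.size();
  std::vector<double> X((size_t)n * 2);
  for (int i = 0; i < n; ++i) { X[2 * i] = init(i, 0); X[2 * i + 1] = init(i, 1); }

  double wmax = 0.0;
  for (R_xlen_t e = 0; e < ne; ++e) wmax = std::max(wmax, ew[e]);
  std::vector<double> eps_per_sample(ne), next_sample(ne);
  for (R_xlen_t e = 0; e < ne; ++e) {
    eps_per_sample[e] = wmax / ew[e];
    next_sample[e] = eps_per_sample[e];
  }

  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  auto clip = [](double x) { return x > 4.0 ? 4.0 : (x < -4.0 ? -4.0 : x); };

  for (int ep = 1; ep <= n_epochs; ++ep) {
    double alpha = lr0 * (1.0 - (double)(ep - 1) / n_epochs);
    for (R_xlen_t e = 0; e < ne; ++e) {
      if (next_sample[e] > ep) continue;
      int i = ei[e], j = ej[e];
      double *xi = &X[2 * i], *xj = &X[2 * j];
      double dx = xi[0] - xj[0], dy = xi[1] - xj[1];
      double d2 = dx * dx + dy * dy;
      if (d2 > 0.0) {
        double pd2b = std::pow(d2, b);
        double gc = (-2.0 * a * b * pd2b / d2) / (a * pd2b + 1.0);
        double gx = clip(gc * dx), gy = clip(gc * dy);
        xi[0] += alpha * gx; xi[1] += alpha * gy;
        xj[0] -= alpha * gx; xj[1] -= alpha * gy;
      }
      for (int s = 0; s < negative; ++s) {
        int k = (int)(unif(rng) * n) % n;
        if (k == i) continue;
        double *xk = &X[2 * k];
        double rx = xi[0] - xk[0], ry = xi[1] - xk[1];
        double r2 = rx * rx + ry * ry;
        double pr2b = std::pow(r2, b);
        double gc = (2.0 * b) / ((0.001 + r2) * (a * pr2b + 1.0));
        double gx = clip(gc * rx), gy = clip(gc * ry);
        xi[0] += alpha * gx; xi[1] += alpha * gy;
      }
      next_sample[e] += eps_per_sample[e];
    }
    Rcpp::checkUserInterrupt();
  }
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) { out(i, 0) = X[2 * i]; out(i, 1) = X[2 * i + 1]; }
  return out;
}

// Smooth-knn edge weights: for each row of knn distances, find rho (distance
// to nearest neighbor) and sigma solving sum_j exp(-(d_ij - rho)/sigma) =
// log2(k) by bisection, then return the membership weights.
// [[Rcpp::export]]
NumericMatrix cpp_smooth_knn_weights(NumericMatrix D) {
  const int n = D.nrow(), k = D.ncol();
  const double target = std::log2((double)k);
  NumericMatrix W(n, k);
  for (int i = 0; i < n; ++i) {
    double rho = D(i, 0);
    for (int j = 0; j < k; ++j) if (D(i, j) > 0) { rho = D(i, j); break; }
    double lo = 1e-12, hi = 1e3 * (D(i, k - 1) + 1e-12), sigma = 1.0;
    for (int it = 0; it < 64; ++it) {
      sigma = 0.5 * (lo + hi);
      double s = 0.0;
      for (int j = 0; j < k; ++j) {
        double d = D(i, j) - rho;
        s += d <= 0 ? 1.0 : std::exp(-d / sigma);
      }
      if (s > target) hi = sigma; else lo = sigma;
    }
    for (int j = 0; j < k; ++j) {
      double d = D(i, j) - rho;
      W(i, j) = d <= 0 ? 1.0 : std::exp(-d / sigma);
    }
  }
  return W;
}
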