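#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Skip-gram with negative sampling over a walk corpus.
//
// The objective being approximated is the corpus log-likelihood of observing
// each node's walk neighborhood given its vector, with the full softmax
// replaced by k negative samples drawn from the unigram^0.75 distribution.
// Single-threaded, deterministic for a fixed seed. Returns the input-side
// vectors (one row per node) plus a per-epoch mean negative log-likelihood
// trace.

static const int EXP_TABLE_SIZE = 1000;
static const double MAX_EXP = 6.0;

// [[Rcpp::export]]
List cpp_sgns(IntegerMatrix walks, int n_nodes, int dim, int window,
              int epochs, int negative, double alpha0, double alpha_min,
              double seed) {
  const R_xlen_t n_walks = walks.nrow();
  const int wl = walks.ncol();

  // sigmoid lookup
  std::vector<double> sigt(EXP_TABLE_SIZE);
  for (int i = 0; i < EXP_TABLE_SIZE; ++i) {
    double x = (i / (double)EXP_TABLE_SIZE * 2.0 - 1.0) * MAX_EXP;
    double e = std::exp(x);
    sigt[i] = e / (e + 1.0);
  }
  auto sigmoid = [&](double x) -> double {
    if (x >= MAX_EXP) return 1.0;
    if (x <= -MAX_EXP) return 0.0;
    return sigt[(int)((x + MAX_EXP) / (2.0 * MAX_EXP) * (EXP_TABLE_SIZE - 1))];
  };

  // unigram^0.75 cumulative table for negative sampling
  std::vector<double> freq(n_nodes, 0.0);
  for (R_xlen_t r = 0; r < n_walks; ++r)
    for (int c = 0; c < wl; ++c) freq[walks(r, c)] += 1.0;
  std::vector<double> cum(n_nodes);
  double tot = 0.0;
  for (int i = 0; i < n_nodes; ++i) {
    tot += std::pow(freq[i], 0.75);
    cum[i] = tot;
  }

  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  auto draw_neg = [&]() -> int {
    double u = unif(rng) * tot;
    int a = 0, b = n_nodes - 1;
    while (a < b) {
      int mid = (a + b) / 2;
      if (cum[mid] < u) a = mid + 1; else b = mid;
    }
    return a;
  };

  std::vector<double> syn0((size_t)n_nodes * dim);
  std::vector<double> syn1((size_t)n_nodes * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (unif(rng) - 0.5) / dim;

  const double total_tokens = (double)n_walks * wl * epochs;
  double seen = 0.0;
  NumericVector loss_trace(epochs);
  std::vector<double> grad(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    double loss = 0.0, npairs = 0.0;
    for (R_xlen_t r = 0; r < n_walks; ++r) {
      for (int t = 0; t < wl; ++t, seen += 1.0) {
        double alpha = alpha0 * (1.0 - seen / total_tokens);
        if (alpha < alpha_min) alpha = alpha_min;
        int b = 1 + (int)(unif(rng) * window);  // reduced window 1..window
        int center = walks(r, t);
        double *v_c = &syn0[(size_t)center * dim];
        for (int off = -b; off <= b; ++off) {
          if (off == 0) continue;
          int cpos = t + off;
          if (cpos < 0 || cpos >= wl) continue;
          int ctx = walks(r, cpos);
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int s = 0; s <= negative; ++s) {
            int target; double label;
            if (s == 0) { target = ctx; label = 1.0; }
            else {
              target = draw_neg();
              if (target == ctx) continue;
              label = 0.0;
            }
            double *v_o = &syn1[(size_t)target * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += v_c[d] * v_o[d];
            double p = sigmoid(dot);
            double g = (label - p) * alpha;
            loss += label > 0.5 ? -std::log(std::max(p, 1e-12))
                                : -std::log(std::max(1.0 - p, 1e-12));
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * v_o[d];
              v_o[d] += g * v_c[d];
            }
          }
          for (int d = 0; d < dim; ++d) v_c[d] += grad[d];
          npairs += 1.0;
        }
      }
    }
    loss_trace[ep] = npairs > 0 ? loss / npairs : NA_REAL;
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix emb(n_nodes, dim);
  for (int i = 0; i < n_nodes; ++i)
    for (int d = 0; d < dim; ++d) emb(i, d) = syn0[(size_t)i * dim + d];
  return List::create(_["embedding"] = emb, _["loss"] = loss_trace);
}
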