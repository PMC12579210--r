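#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Random walks over a CSR graph. xadj: n+1 offsets (0-based), adjncy:
// neighbor ids (0-based). cumw: per-node cumulative edge weights aligned
// with adjncy (ignored when weighted = false). Walks are rows of the
// returned matrix, walk_length steps = walk_length + 1 nodes, 0-based ids.
// Walk order: for each pass w = 1..walks_per_node, nodes in id order, so
// the corpus interleaves start nodes evenly across training.
// [[Rcpp::export]]
IntegerMatrix cpp_sample_walks(IntegerVector xadj, IntegerVector adjncy,
                               NumericVector cumw, bool weighted,
                               int walks_per_node, int walk_length,
                               double seed) {
  const int n = xadj.size() - 1;
  std::mt19937_64 rng((uint64_t)seed);
  IntegerMatrix walks((R_xlen_t)n * walks_per_node, walk_length + 1);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  R_xlen_t row = 0;
  for (int w = 0; w < walks_per_node; ++w) {
    for (int v0 = 0; v0 < n; ++v0, ++row) {
      int cur = v0;
      walks(row, 0) = cur;
      for (int s = 1; s <= walk_length; ++s) {
        int lo = xadj[cur], hi = xadj[cur + 1];
        int deg = hi - lo;
        if (deg <= 0) stop("isolated node encountered during walk");
        int nxt;
        if (!weighted) {
          nxt = adjncy[lo + (int)(unif(rng) * deg) % deg];
        } else {
          double total = cumw[hi - 1] - (lo > 0 ? cumw[lo - 1] : 0.0);
          double u = unif(rng) * total + (lo > 0 ? cumw[lo - 1] : 0.0);
          // binary search in cumw[lo..hi-1]
          int a = lo, b = hi - 1;
          while (a < b) {
            int mid = (a + b) / 2;
            if (cumw[mid] < u) a = mid + 1; else b = mid;
          }
          nxt = adjncy[a];
        }
        walks(row, s) = nxt;
        cur = nxt;
      }
    }
  }
  return walks;
}
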