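#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <random>
#include <vector>

using namespace Rcpp;

// Greedy two-phase Louvain on a dense generalised modularity matrix.
// Maximises sum_ij B(i,j) * delta(sigma_i, sigma_j); B must be symmetric.
// Diagonal terms are constant across partitions and never enter move gains.
// Tie-break: a node moves only on a strict gain (> 1e-12), otherwise it keeps
// its current community. Node visitation order is reshuffled every pass from
// the seed, so results are deterministic given (B, seed).
// [[Rcpp::export]]
IntegerVector louvain_matrix_cpp(NumericMatrix B, int seed) {
  const int n = B.nrow();
  if (B.ncol() != n) stop("modularity matrix must be square");
  std::mt19937 rng(static_cast<unsigned int>(seed));

  // working aggregated matrix, flat row-major
  std::vector<double> M(B.begin(), B.end());  // column-major, symmetric so fine
  int m = n;                                   // current number of supernodes
  std::vector<int> orig(n);                    // original node -> supernode
  std::iota(orig.begin(), orig.end(), 0);

  for (int level = 0; level < n + 1; ++level) {
    std::vector<int> comm(m);
    std::iota(comm.begin(), comm.end(), 0);
    std::vector<int> order(m);
    std::iota(order.begin(), order.end(), 0);

    bool any_move = false;
    bool improved = true;
    int pass = 0;
    std::vector<double> s(m);
    while (improved && pass++ < 1000) {
      improved = false;
      std::shuffle(order.begin(), order.end(), rng);
      for (int oi = 0; oi < m; ++oi) {
        const int i = order[oi];
        std::fill(s.begin(), s.end(), 0.0);
        for (int j = 0; j < m; ++j) {
          if (j != i) s[comm[j]] += M[(size_t)j * m + i];
        }
        const int cur = comm[i];
        int best = cur;
        double best_gain = s[cur];
        for (int c = 0; c < m; ++c) {
          if (s[c] > best_gain + 1e-12) { best = c; best_gain = s[c]; }
        }
        if (best != cur) {
          comm[i] = best;
          improved = true;
          any_move = true;
        }
      }
    }
    if (!any_move) break;

    // relabel communities 0..k-1 by first occurrence
    std::vector<int> relab(m, -1);
    int k = 0;
    for (int i = 0; i < m; ++i) {
      if (relab[comm[i]] < 0) relab[comm[i]] = k++;
      comm[i] = relab[comm[i]];
    }
    for (int o = 0; o < n; ++o) orig[o] = comm[orig[o]];
    if (k == m) break;  // no aggregation possible

    // aggregate: Mnew(a,b) = sum_{i in a, j in b} M(i,j)
    std::vector<double> Mnew((size_t)k * k, 0.0);
    for (int j = 0; j < m; ++j) {
      const int cj = comm[j];
      for (int i = 0; i < m; ++i) {
        Mnew[(size_t)cj * k + comm[i]] += M[(size_t)j * m + i];
      }
    }
    M.swap(Mnew);
    m = k;
  }

  // final labels 1..k by first occurrence over original nodes
  std::vector<int> relab(m >= 1 ? m : 1, -1);
  int k = 0;
  IntegerVector out(n);
  for (int o = 0; o < n; ++o) {
    if (relab[orig[o]] < 0) relab[orig[o]] = ++k;
    out[o] = relab[orig[o]];
  }
  return out;
}
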