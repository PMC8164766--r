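// Weighted base-pair-maximization folding (Nussinov-style dynamic program).
//
// Pair weights: GC/CG = 3, AU/UA = 2, GU/UG = 1; minimum hairpin loop 3 nt;
// no pseudoknots.  An optional position-pair scale matrix multiplies the
// base weight (used for consensus folding with per-column compatibility
// penalties).  Traceback is deterministic: at each interval, pairing is
// preferred over leaving the right end unpaired, and among pairing partners
// the one spanning the longest interval (leftmost k for (k, j)) wins.

#include <Rcpp.h>
using namespace Rcpp;

static inline double base_weight(int a, int b) {
  // bases encoded A=1, C=2, G=3, U=4
  if ((a == 3 && b == 2) || (a == 2 && b == 3)) return 3.0;
  if ((a == 1 && b == 4) || (a == 4 && b == 1)) return 2.0;
  if ((a == 3 && b == 4) || (a == 4 && b == 3)) return 1.0;
  return 0.0;
}

// [[Rcpp::export(name = ".nussinov_cpp")]]
List nussinov_cpp(IntegerVector seq, Nullable<NumericMatrix> scale,
                  int min_loop) {
  const int n = seq.size();
  IntegerVector partner(n, -1);
  if (n == 0)
    return List::create(_["score"] = 0.0, _["partner"] = partner);

  NumericMatrix sc;
  bool has_scale = scale.isNotNull();
  if (has_scale) sc = NumericMatrix(scale);

  auto W = [&](int i, int j) -> double {  // 0-based
    double w = base_weight(seq[i], seq[j]);
    if (w <= 0.0) return 0.0;
    if (has_scale) w *= sc(i, j);
    return w;
  };

  // M[i][j] stored in a flat vector, i <= j
  std::vector<double> M((size_t)n * n, 0.0);
  auto at = [&](int i, int j) -> double& { return M[(size_t)i * n + j]; };

  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double best = at(i, j - 1);  // j unpaired
      for (int k = i; k <= j - min_loop - 1; ++k) {
        double w = W(k, j);
        if (w <= 0.0) continue;
        double v = w;
        if (k > i) v += at(i, k - 1);
        if (k + 1 <= j - 1) v += at(k + 1, j - 1);
        if (v > best) best = v;
      }
      at(i, j) = best;
    }
  }

  // deterministic traceback
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  const double eps = 1e-9;
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i < min_loop + 1) continue;
    double target = at(i, j);
    if (target <= 0.0) continue;
    bool done = false;
    for (int k = i; k <= j - min_loop - 1 && !done; ++k) {
      double w = W(k, j);
      if (w <= 0.0) continue;
      double v = w;
      if (k > i) v += at(i, k - 1);
      if (k + 1 <= j - 1) v += at(k + 1, j - 1);
      if (std::abs(v - target) < eps) {
        partner[k] = j;
        partner[j] = k;
        if (k > i) stack.push_back(std::make_pair(i, k - 1));
        if (k + 1 <= j - 1) stack.push_back(std::make_pair(k + 1, j - 1));
        done = true;
      }
    }
    if (!done) stack.push_back(std::make_pair(i, j - 1));
  }

  return List::create(_["score"] = at(0, n - 1), _["partner"] = partner);
}
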