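#include <Rcpp.h>
using namespace Rcpp;

// Dynamic-programming kernel for dynamic time warping.
//
// `cost` is the precomputed local cost matrix (n x m). `sym2` selects the
// symmetric2 step pattern (diagonal transitions weighted twice); otherwise
// symmetric1 (all transitions weight 1). `window` is a Sakoe-Chiba radius
// (|i - j| <= window); a negative value means unconstrained. Returns the
// minimum cumulative cost, or +Inf if the window admits no path.
// [[Rcpp::export(name = ".dtwDp")]]
double dtw_dp(NumericMatrix cost, bool sym2, int window) {
  const int n = cost.nrow(), m = cost.ncol();
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> prev(m, inf), cur(m, inf);

  for (int i = 0; i < n; ++i) {
    std::fill(cur.begin(), cur.end(), inf);
    int jlo = 0, jhi = m - 1;
    if (window >= 0) {
      jlo = std::max(0, i - window);
      jhi = std::min(m - 1, i + window);
    }
    for (int j = jlo; j <= jhi; ++j) {
      const double c = cost(i, j);
      double best;
      if (i == 0 && j == 0) {
        best = c;
      } else {
        best = inf;
        if (i > 0 && prev[j] + c < best) best = prev[j] + c;         // vertical
        if (j > 0 && cur[j - 1] + c < best) best = cur[j - 1] + c;   // horizontal
        if (i > 0 && j > 0) {
          const double diag = prev[j - 1] + (sym2 ? 2.0 : 1.0) * c;  // diagonal
          if (diag < best) best = diag;
        }
      }
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}
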