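#include <Rcpp.h>
#include <vector>
#include <limits>

// Hungarian algorithm (shortest augmenting path with dual potentials),
// O(n^3), minimising total cost of a square assignment. Handles negative
// entries, which the transfer-distance reduction relies on (negated overlaps).
// a: row-major n*n. Returns ans[i] = column matched to row i (0-based).
std::vector<int> hungarian_min(const std::vector<double>& a, int n) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = a[(i0 - 1) * n + (j - 1)] - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  std::vector<int> ans(n);
  for (int j = 1; j <= n; ++j) if (p[j] > 0) ans[p[j] - 1] = j - 1;
  return ans;
}

// [[Rcpp::export]]
Rcpp::IntegerVector solve_lsap_cpp(Rcpp::NumericMatrix cost) {
  int n = cost.nrow();
  std::vector<double> a(n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      a[i * n + j] = cost(i, j);
  std::vector<int> ans = hungarian_min(a, n);
  Rcpp::IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = ans[i] + 1;  // 1-based for R
  return out;
}
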