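#include <Rcpp.h>
#include <vector>
#include <limits>

// Minimum-cost perfect assignment on a square cost matrix via the
// Jonker-Volgenant shortest-augmenting-path scheme with dual potentials
// (O(n^3)). Deterministic: rows are introduced in order, and among equal
// reduced costs the lowest column index wins, so equal-cost optima resolve
// to the lexicographically first assignment.
//
// Returns a 1-based column index for every row.
// [[Rcpp::export]]
Rcpp::IntegerVector lap_solve(Rcpp::NumericMatrix cost) {
  const int n = cost.nrow();
  if (cost.ncol() != n) Rcpp::stop("cost matrix must be square");
  Rcpp::IntegerVector rowsol(n);
  if (n == 0) return rowsol;

  const double INF = std::numeric_limits<double>::infinity();
  // 1-based with sentinel index 0
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0), minv(n + 1);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  std::vector<char> used(n + 1);

  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::fill(minv.begin(), minv.end(), INF);
    std::fill(used.begin(), used.end(), 0);
    do {
      used[j0] = 1;
      const int i0 = p[j0];
      double delta = INF;
      int j1 = -1;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        const double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else           minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do {
      const int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0);
  }
  for (int j = 1; j <= n; ++j)
    if (p[j] > 0) rowsol[p[j] - 1] = j;
  return rowsol;
}
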