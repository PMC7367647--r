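#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Circular binary segmentation statistic.
//
// For a vector x of length n, candidate splits are circular arcs (i, j]
// (0-based cut positions, 0 <= i < j <= n) holding the positions i+1..j;
// the complement wraps around. The statistic is the pooled two-sample t
// between arc and complement. Both parts must contain >= min_width points.
//
// Degenerate pooled variance (both parts internally constant) is floored so
// a perfect noiseless step yields a very large finite t rather than NaN.

static const double VAR_FLOOR = 1e-24;

// t statistic for arc (i, j]; S, Q are prefix sums of x and x^2.
static inline double arc_t(const double* S, const double* Q, int n,
                           int i, int j) {
  const int k = j - i;
  const int m = n - k;
  const double sumA = S[j] - S[i];
  const double sumB = S[n] - sumA;
  const double qA = Q[j] - Q[i];
  const double qB = Q[n] - qA;
  const double meanA = sumA / k;
  const double meanB = sumB / m;
  const double diff = meanA - meanB;
  // a mean difference at rounding-noise scale is a tie, not a split
  const double scale = std::max(std::fabs(meanA), std::fabs(meanB));
  if (std::fabs(diff) <= 1e-9 * scale || diff == 0.0) return 0.0;
  double pooled = (qA - k * meanA * meanA) + (qB - m * meanB * meanB);
  pooled /= (n - 2);
  if (pooled < VAR_FLOOR) pooled = VAR_FLOOR;
  const double se = std::sqrt(pooled * (1.0 / k + 1.0 / m));
  return diff / se;
}

// Exhaustive scan over all valid arcs; ties broken by smallest (i, j).
// Cut position n is identical to cut position 0 on the circle, so arcs
// ending at j == n would duplicate the (0, i] partitions; the scan is
// restricted to j <= n-1 so every partition is visited exactly once.
static void max_t_scan(const double* S, const double* Q, int n,
                       int min_width, int& best_i, int& best_j,
                       double& best_t) {
  best_i = -1; best_j = -1; best_t = 0.0;
  double best_abs = -1.0;
  for (int i = 0; i <= n - 1; ++i) {
    const int j_lo = i + min_width;
    int j_hi = i + (n - min_width);
    if (j_hi > n - 1) j_hi = n - 1;
    for (int j = j_lo; j <= j_hi; ++j) {
      const double t = arc_t(S, Q, n, i, j);
      const double a = std::fabs(t);
      if (a > best_abs) {  // strict: keeps lexicographically smallest (i, j)
        best_abs = a; best_t = t; best_i = i; best_j = j;
      }
    }
  }
}

static void prefix_sums(const NumericVector& x, std::vector<double>& S,
                        std::vector<double>& Q) {
  const int n = x.size();
  S.assign(n + 1, 0.0);
  Q.assign(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    S[i + 1] = S[i] + x[i];
    Q[i + 1] = Q[i] + x[i] * x[i];
  }
}

// [[Rcpp::export]]
List cpp_max_circular_t(NumericVector x, int min_width) {
  const int n = x.size();
  if (n < 2 * min_width)
    return List::create(_["i"] = NA_INTEGER, _["j"] = NA_INTEGER,
                        _["t"] = NA_REAL);
  std::vector<double> S, Q;
  prefix_sums(x, S, Q);
  int bi, bj; double bt;
  max_t_scan(S.data(), Q.data(), n, min_width, bi, bj, bt);
  return List::create(_["i"] = bi, _["j"] = bj, _["t"] = bt);
}

// Permutation p-value for the maximal circular t.
//
// p = (1 + #{perm max |t*| >= |observed|}) / (n_perm + 1).
// Uses R's RNG (unif_rand) so set.seed() governs reproducibility.
// If early_alpha > 0, permutation stops as soon as enough exceedances have
// accumulated to guarantee the full-run p would be >= early_alpha; the
// returned p is then the sequential estimate (1 + e) / (k + 1) — the
// accept/reject decision at early_alpha is unchanged.
// [[Rcpp::export]]
List cpp_permutation_p(NumericVector x, double observed_abs_t, int n_perm,
                       int min_width, double early_alpha) {
  const int n = x.size();
  std::vector<double> work(x.begin(), x.end());
  std::vector<double> S, Q;
  int exceed = 0, used = 0;
  const int stop_at = early_alpha > 0
    ? (int)std::ceil(early_alpha * (n_perm + 1)) : n_perm + 1;
  NumericVector xv(n);
  for (int p = 0; p < n_perm; ++p) {
    // Fisher-Yates shuffle
    for (int i = n - 1; i > 0; --i) {
      int k = (int)(unif_rand() * (i + 1));
      if (k > i) k = i;
      std::swap(work[i], work[k]);
    }
    for (int i = 0; i < n; ++i) xv[i] = work[i];
    prefix_sums(xv, S, Q);
    int bi, bj; double bt;
    max_t_scan(S.data(), Q.data(), n, min_width, bi, bj, bt);
    ++used;
    if (std::fabs(bt) >= observed_abs_t) {
      ++exceed;
      if (exceed >= stop_at) break;
    }
  }
  const double denom = (used == n_perm) ? (n_perm + 1) : (used + 1);
  return List::create(_["p"] = (1.0 + exceed) / denom,
                      _["n_used"] = used, _["n_exceed"] = exceed);
}
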