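#include <Rcpp.h>
#include <algorithm>
#include <random>
using namespace Rcpp;

// Strasser-Weber standardized linear association statistic between one
// covariate x and the response y over the rows of a node, with its
// permutation-null mean/variance computed in closed form.
static inline void assoc_one(const double* x, const double* y,
                             const int* rows, const int m,
                             double& z, double& pval) {
  double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
  for (int r = 0; r < m; ++r) {
    const double xi = x[rows[r]], yi = y[rows[r]];
    sx += xi; sy += yi; sxx += xi * xi; syy += yi * yi; sxy += xi * yi;
  }
  const double vx = sxx - sx * sx / m;
  const double vy = syy - sy * sy / m;
  if (vx <= 1e-12 || vy <= 1e-12 || m < 2) { z = 0.0; pval = 1.0; return; }
  const double mu = sx * sy / m;
  const double sigma2 = vx * vy / (m - 1);
  z = (sxy - mu) / std::sqrt(sigma2);
  pval = 2.0 * R::pnorm(-std::fabs(z), 0.0, 1.0, 1, 0);
}

// Per-variable association z and unadjusted two-sided asymptotic p-values
// at one node. rows: 0-based indices into the rows of X.
// [[Rcpp::export]]
List cit_assoc_cpp(NumericMatrix X, NumericVector y, IntegerVector rows) {
  const int k = X.ncol(), m = rows.size();
  NumericVector z(k), p(k);
  for (int j = 0; j < k; ++j) {
    double zj, pj;
    assoc_one(&X(0, j), y.begin(), rows.begin(), m, zj, pj);
    z[j] = zj; p[j] = pj;
  }
  return List::create(_["z"] = z, _["p"] = p);
}

// Monte-Carlo permutation p-value for the same statistic (response
// permutation, deterministic given seed).
// [[Rcpp::export]]
double cit_perm_pvalue_cpp(NumericVector x, NumericVector y,
                           int n_perm, int seed) {
  const int n = x.size();
  double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
  for (int i = 0; i < n; ++i) {
    sx += x[i]; sy += y[i]; sxx += x[i] * x[i];
    syy += y[i] * y[i]; sxy += x[i] * y[i];
  }
  const double vx = sxx - sx * sx / n, vy = syy - sy * sy / n;
  if (vx <= 1e-12 || vy <= 1e-12) return 1.0;
  const double t_obs = std::fabs(sxy - sx * sy / n);
  std::vector<double> yp(y.begin(), y.end());
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  int hits = 0;
  for (int b = 0; b < n_perm; ++b) {
    std::shuffle(yp.begin(), yp.end(), rng);
    double t = 0;
    for (int i = 0; i < n; ++i) t += x[i] * yp[i];
    if (std::fabs(t - sx * sy / n) >= t_obs - 1e-12) ++hits;
  }
  return (1.0 + hits) / (1.0 + n_perm);
}

// Exhaustive split-point search on one variable: maximizes the absolute
// standardized two-sample statistic over all cutpoints keeping at least
// minbucket observations on each side. Ties broken toward the smallest
// cutpoint. Returns split point (midpoint of adjacent distinct values),
// the achieved |z|, and feasibility flag.
// [[Rcpp::export]]
List cit_split_cpp(NumericVector x, NumericVector y, IntegerVector rows,
                   int minbucket) {
  const int m = rows.size();
  std::vector<int> ord(m);
  for (int i = 0; i < m; ++i) ord[i] = rows[i];
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return x[a] < x[b]; });
  double sy = 0, syy = 0;
  for (int i = 0; i < m; ++i) { sy += y[ord[i]]; syy += y[ord[i]] * y[ord[i]]; }
  const double ybar = sy / m;
  const double ssy = syy - sy * sy / m;
  if (ssy <= 1e-12 || m < 2 * minbucket)
    return List::create(_["ok"] = false, _["point"] = NA_REAL,
                        _["stat"] = NA_REAL);
  double best = -1.0, best_point = NA_REAL;
  double cum = 0;
  for (int i = 0; i < m - 1; ++i) {
    cum += y[ord[i]];
    const int nl = i + 1, nr = m - nl;
    if (nl < minbucket || nr < minbucket) continue;
    if (x[ord[i]] >= x[ord[i + 1]]) continue;  // not a distinct boundary
    const double mu = nl * ybar;
    const double sig2 = (double)nl * nr / ((double)m * (m - 1)) * ssy;
    const double zi = std::fabs(cum - mu) / std::sqrt(sig2);
    if (zi > best + 1e-12) {
      best = zi;
      best_point = 0.5 * (x[ord[i]] + x[ord[i + 1]]);
    }
  }
  if (best < 0)
    return List::create(_["ok"] = false, _["point"] = NA_REAL,
                        _["stat"] = NA_REAL);
  return List::create(_["ok"] = true, _["point"] = best_point,
                      _["stat"] = best);
}
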