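// Forward-search core of Hadi's multivariate outlier detection.
// The per-record growth loop (covariance re-estimation + re-ranking at each
// subset size) is O(n) iterations and dominates the simulation suites, so it
// lives in compiled code.  All validation happens in the R wrapper.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <algorithm>
#include <utility>
#include <vector>

using namespace Rcpp;

// squared Mahalanobis-type distances of rows of X about centre m with
// scatter C (via Cholesky); returns false on a non-PD scatter
static bool quad_dist(const arma::mat& X, const arma::rowvec& m,
                      const arma::mat& C, arma::vec& out) {
  arma::mat R;
  if (!arma::chol(R, C)) return false;
  arma::mat Xc = X.each_row() - m;
  arma::mat Y = arma::solve(arma::trimatl(R.t()), Xc.t());
  out = arma::sum(Y % Y, 0).t();
  return true;
}

typedef std::pair<double, arma::uword> dpair;  // (distance, index): ties by index

// partition `pairs` so its first r entries are the r smallest (deterministic
// under ties); returns the candidate just outside the subset via `next`
static void select_r(std::vector<dpair>& pairs, arma::uword r) {
  if (r < pairs.size())
    std::nth_element(pairs.begin(), pairs.begin() + r, pairs.end());
}

// [[Rcpp::export(name = ".hadi_forward")]]
List hadi_forward(const arma::mat& X, double alpha) {
  const arma::uword n = X.n_rows, p = X.n_cols;

  // step 1: order by distance from the coordinate-wise median, scatter about
  // the median
  arma::rowvec med = arma::median(X, 0);
  arma::mat Xm = X.each_row() - med;
  arma::mat S0 = (Xm.t() * Xm) / double(n - 1);
  arma::vec d;
  if (!quad_dist(X, med, S0, d)) {
    return List::create(_["singular"] = true, _["where"] = "initial median scatter");
  }

  std::vector<dpair> pairs(n);
  for (arma::uword i = 0; i < n; ++i) pairs[i] = dpair(d(i), i);

  const arma::uword h = (n + p + 1) / 2;
  double cnp = 1.0 + double(p + 1) / double(n - p);
  if (double(n) - 1.0 - 3.0 * double(p) > 0.0)
    cnp += 2.0 / (double(n) - 1.0 - 3.0 * double(p));
  const double cutoff = R::qchisq(1.0 - alpha / double(n), double(p), 1, 0);

  std::vector<int> trace;
  arma::uword r = p + 1;
  bool have_d = false;

  // forward search: grow the basic subset to h records, then keep admitting
  // records while the smallest outside corrected distance stays below the
  // chi-square cutoff
  while (true) {
    select_r(pairs, r);
    arma::mat Xi(r, p);
    for (arma::uword i = 0; i < r; ++i) Xi.row(i) = X.row(pairs[i].second);
    arma::rowvec m = arma::mean(Xi, 0);
    arma::mat C = arma::cov(Xi);
    arma::vec dn;
    if (!quad_dist(X, m, C, dn)) {
      if (r < h) { ++r; continue; }           // singular: admit one more
      return List::create(_["singular"] = true,
                          _["where"] = "basic-subset covariance");
    }
    d = dn;
    for (arma::uword i = 0; i < n; ++i) pairs[i] = dpair(d(i), i);
    trace.push_back(int(r));
    have_d = true;
    if (r < h) { ++r; continue; }
    if (r >= n) break;
    select_r(pairs, r);
    if (pairs[r].first / cnp > cutoff) break;  // next candidate is an outlier
    ++r;
  }
  if (!have_d) {
    return List::create(_["singular"] = true,
                        _["where"] = "basic-subset covariance");
  }

  arma::vec dist = d / cnp;
  LogicalVector flags(n);
  for (arma::uword i = 0; i < n; ++i) flags[i] = dist(i) > cutoff;

  return List::create(
    _["singular"] = false,
    _["distances"] = NumericVector(dist.begin(), dist.end()),
    _["cutoff"] = cutoff,
    _["flags"] = flags,
    _["trace"] = wrap(trace),
    _["subset_size"] = int(r));
}
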