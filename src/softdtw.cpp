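// Soft dynamic time warping: smoothed-min DP recursion, its gradient with
// respect to the first series (forward-backward pass), and batched drivers
// used by the soft-DTW K-means baseline.  Series are time x channels.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double softmin3(double a, double b, double c, double inv_gamma,
                              double gamma) {
  double mn = std::min(a, std::min(b, c));
  if (!std::isfinite(mn)) return mn;
  // One of the three terms is exp(0) = 1.
  double s = 1.0;
  if (a != mn) s += std::exp((mn - a) * inv_gamma);
  if (b != mn) s += std::exp((mn - b) * inv_gamma);
  if (c != mn) s += std::exp((mn - c) * inv_gamma);
  // Guard against double-counting when two entries tie at the minimum: the
  // branch above only adds non-minimal terms, ties contribute exp(0) once
  // here instead of being skipped.
  int ties = (a == mn) + (b == mn) + (c == mn);
  s += ties - 1;
  return mn - gamma * std::log(s);
}

// Squared-Euclidean local cost matrix.
static mat cost_matrix(const mat& x, const mat& y) {
  vec xs = sum(square(x), 1);
  vec ys = sum(square(y), 1);
  mat D = repmat(xs, 1, y.n_rows) + repmat(ys.t(), x.n_rows, 1) -
          2.0 * x * y.t();
  D.clamp(0.0, datum::inf);
  return D;
}

static mat forward_pass(const mat& D, double gamma) {
  const uword n = D.n_rows, m = D.n_cols;
  const double inv_gamma = 1.0 / gamma;
  mat R(n + 1, m + 1);
  R.fill(datum::inf);
  R(0, 0) = 0.0;
  for (uword j = 1; j <= m; ++j) {
    const double* dcol = D.colptr(j - 1);
    const double* rprev = R.colptr(j - 1);
    double* rcur = R.colptr(j);
    for (uword i = 1; i <= n; ++i)
      rcur[i] = dcol[i - 1] +
                softmin3(rcur[i - 1], rprev[i], rprev[i - 1], inv_gamma,
                         gamma);
  }
  return R;
}

// [[Rcpp::export]]
double cpp_softdtw(const arma::mat& x, const arma::mat& y, double gamma) {
  mat D = cost_matrix(x, y);
  mat R = forward_pass(D, gamma);
  return R(x.n_rows, y.n_rows);
}

// Backward pass (alignment expectation matrix E), then chain rule through the
// squared-Euclidean cost: d sdtw / d x_i = sum_j E_ij * 2 (x_i - y_j).
static void sdtw_value_grad(const mat& x, const mat& y, double gamma,
                            double& value, mat& grad) {
  const uword n = x.n_rows, m = y.n_rows;
  mat D = cost_matrix(x, y);
  mat R = forward_pass(D, gamma);
  value = R(n, m);

  mat Dp(n + 2, m + 2, fill::zeros);
  Dp.submat(1, 1, n, m) = D;
  mat Rp(n + 2, m + 2);
  Rp.fill(-datum::inf);
  Rp.submat(0, 0, n, m) = R;
  // Convert unreachable inf entries to -inf so their weights vanish.
  Rp.elem(find(Rp == datum::inf)).fill(-datum::inf);
  Rp(n + 1, m + 1) = R(n, m);

  mat E(n + 2, m + 2, fill::zeros);
  E(n + 1, m + 1) = 1.0;
  const double inv_gamma = 1.0 / gamma;
  for (uword j = m; j >= 1; --j) {
    const double* rj = Rp.colptr(j);
    const double* rj1 = Rp.colptr(j + 1);
    const double* dj = Dp.colptr(j);
    const double* dj1 = Dp.colptr(j + 1);
    double* ej = E.colptr(j);
    const double* ej1 = E.colptr(j + 1);
    for (uword i = n; i >= 1; --i) {
      double a = std::exp((rj[i + 1] - rj[i] - dj[i + 1]) * inv_gamma);
      double b = std::exp((rj1[i] - rj[i] - dj1[i]) * inv_gamma);
      double c = std::exp((rj1[i + 1] - rj[i] - dj1[i + 1]) * inv_gamma);
      if (!std::isfinite(a)) a = 0.0;
      if (!std::isfinite(b)) b = 0.0;
      if (!std::isfinite(c)) c = 0.0;
      ej[i] = ej[i + 1] * a + ej1[i] * b + ej1[i + 1] * c;
    }
  }
  mat Ein = E.submat(1, 1, n, m);
  grad = 2.0 * (x.each_col() % sum(Ein, 1)) - 2.0 * Ein * y;
}

// [[Rcpp::export]]
Rcpp::List cpp_softdtw_grad(const arma::mat& x, const arma::mat& y,
                            double gamma) {
  double value;
  mat grad;
  sdtw_value_grad(x, y, gamma, value, grad);
  return Rcpp::List::create(Rcpp::Named("value") = value,
                            Rcpp::Named("grad") = grad);
}

// Soft-DTW values between every segment (slices of a t x d x m cube) and
// every center (slices of a t x d x s cube).
// [[Rcpp::export]]
arma::mat cpp_softdtw_cross(const arma::cube& segs, const arma::cube& centers,
                            double gamma) {
  const uword m = segs.n_slices, s = centers.n_slices;
  mat out(m, s);
  for (uword i = 0; i < m; ++i)
    for (uword j = 0; j < s; ++j)
      out(i, j) = cpp_softdtw(segs.slice(i), centers.slice(j), gamma);
  return out;
}

// [[Rcpp::export]]
arma::vec cpp_softdtw_self(const arma::cube& segs, double gamma) {
  const uword m = segs.n_slices;
  vec out(m);
  for (uword i = 0; i < m; ++i)
    out(i) = cpp_softdtw(segs.slice(i), segs.slice(i), gamma);
  return out;
}

// Total soft-DTW objective and gradient of a candidate barycenter b against a
// set of member series; used as fn/gr by an L-BFGS barycenter update.
// [[Rcpp::export]]
Rcpp::List cpp_softdtw_barycenter_obj(const arma::mat& b,
                                      const arma::cube& members,
                                      double gamma) {
  double total = 0.0;
  mat gtot(b.n_rows, b.n_cols, fill::zeros);
  for (uword i = 0; i < members.n_slices; ++i) {
    double v;
    mat g;
    sdtw_value_grad(b, members.slice(i), gamma, v, g);
    total += v;
    gtot += g;
  }
  return Rcpp::List::create(Rcpp::Named("value") = total,
                            Rcpp::Named("grad") = gtot);
}
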