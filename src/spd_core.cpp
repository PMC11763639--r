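// Numerical core for SPD-manifold operations on sets of spatial covariance
// matrices.  Matrix functions use symmetric eigendecompositions with an
// eigenvalue floor so near-singular inputs degrade gracefully instead of
// producing NaNs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat sym_fun(const mat& C, double (*f)(double), double floor_ev) {
  vec ev;
  mat V;
  eig_sym(ev, V, symmatu(C));
  ev.transform([&](double v) { return f(std::max(v, floor_ev)); });
  return V * diagmat(ev) * V.t();
}

// expm of a general symmetric matrix: no eigenvalue floor (negative
// eigenvalues are legitimate in tangent space).
static mat sym_expm(const mat& S) {
  vec ev;
  mat V;
  eig_sym(ev, V, symmatu(S));
  return V * diagmat(exp(ev)) * V.t();
}

static double sqrt_(double x) { return std::sqrt(x); }
static double invsqrt_(double x) { return 1.0 / std::sqrt(x); }
static double log_(double x) { return std::log(x); }

// Pairwise sensor-space (max generalized eigenvalue, symmetrized) and
// source-space (affine-invariant Riemannian) distances for m SPD matrices
// stored as an n x n x m cube.  One eigendecomposition per pair serves both:
// the generalized eigenvalues of (Ci, Cj) are the eigenvalues of
// Cj^{-1/2} Ci Cj^{-1/2}, the reverse problem has the reciprocal spectrum,
// and the Riemannian distance is the same for either ordering.
// [[Rcpp::export]]
Rcpp::List cpp_pairwise_spd(const arma::cube& C, double floor_ev) {
  const uword m = C.n_slices;
  mat sensor(m, m, fill::ones);
  mat riem(m, m, fill::zeros);

  std::vector<mat> isq(m);
  for (uword i = 0; i < m; ++i)
    isq[i] = sym_fun(C.slice(i), invsqrt_, floor_ev);

  vec ev;
  for (uword j = 0; j < m; ++j) {
    for (uword i = j + 1; i < m; ++i) {
      mat A = isq[j] * C.slice(i) * isq[j];
      eig_sym(ev, symmatu(A));
      ev = clamp(ev, floor_ev, datum::inf);
      double lmax = ev.max(), lmin = ev.min();
      double s = std::max(lmax, 1.0 / lmin);
      double r = std::sqrt(accu(square(log(ev))));
      sensor(i, j) = sensor(j, i) = s;
      riem(i, j) = riem(j, i) = r;
    }
  }
  return Rcpp::List::create(Rcpp::Named("sensor") = sensor,
                            Rcpp::Named("riemann") = riem);
}

// Karcher flow for the Fréchet (geometric) mean under the affine-invariant
// metric.  Initialized at the arithmetic mean; stops when the Frobenius norm
// of the mean whitened tangent vector drops below tol.
// [[Rcpp::export]]
Rcpp::List cpp_frechet_mean(const arma::cube& C, double tol, int max_iter,
                            double floor_ev) {
  const uword m = C.n_slices;
  mat E = mean(C, 2);
  bool converged = false;
  int used = 0;
  double resid = datum::inf;

  for (int it = 0; it < max_iter; ++it) {
    mat Eisq = sym_fun(E, invsqrt_, floor_ev);
    mat Esq = sym_fun(E, sqrt_, floor_ev);
    mat T(E.n_rows, E.n_cols, fill::zeros);
    for (uword i = 0; i < m; ++i)
      T += sym_fun(Eisq * C.slice(i) * Eisq, log_, floor_ev);
    T /= (double)m;
    resid = norm(T, "fro");
    used = it + 1;
    if (resid <= tol) {
      converged = true;
      break;
    }
    E = Esq * sym_expm(T) * Esq;
    E = symmatu((E + E.t()) / 2.0);
  }
  return Rcpp::List::create(Rcpp::Named("mean") = E,
                            Rcpp::Named("converged") = converged,
                            Rcpp::Named("iterations") = used,
                            Rcpp::Named("residual") = resid);
}

// Logarithm map of every slice of C at base point E, vectorized as the upper
// triangle (diagonal first ordering follows column-major upper indices).
// With weight_sqrt2, off-diagonal entries are scaled by sqrt(2) so Euclidean
// inner products of the vectors equal Frobenius inner products.
// [[Rcpp::export]]
arma::mat cpp_tangent_vectors(const arma::cube& C, const arma::mat& E,
                              bool weight_sqrt2, double floor_ev) {
  const uword m = C.n_slices, n = E.n_rows;
  mat Eisq = sym_fun(E, invsqrt_, floor_ev);
  mat Esq = sym_fun(E, sqrt_, floor_ev);
  const uword p = n * (n + 1) / 2;
  mat out(m, p);
  double w = weight_sqrt2 ? std::sqrt(2.0) : 1.0;
  for (uword i = 0; i < m; ++i) {
    mat L = Esq * sym_fun(Eisq * C.slice(i) * Eisq, log_, floor_ev) * Esq;
    uword k = 0;
    for (uword c = 0; c < n; ++c)
      for (uword r = 0; r <= c; ++r)
        out(i, k++) = (r == c) ? L(r, c) : w * L(r, c);
  }
  return out;
}
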