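// Compiled kernels for orbit iteration, QR-based Lyapunov spectra and
// Hausdorff distances between attractor sample clouds.
// State update throughout: a'(i) = theta(i) + sum_j w(i,j) * tanh(a(j)).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using arma::mat;
using arma::vec;

static inline vec step_vec(const vec& theta, const mat& w, const vec& a) {
  return theta + w * arma::tanh(a);
}

// [[Rcpp::export]]
arma::mat iterate_cpp(const arma::vec& theta, const arma::mat& w,
                      const arma::vec& a0, int n_transient, int n_record) {
  vec a = a0;
  for (int t = 0; t < n_transient; ++t) a = step_vec(theta, w, a);
  mat out(n_record, a.n_elem);
  out.row(0) = a.t();
  for (int t = 1; t < n_record; ++t) {
    a = step_vec(theta, w, a);
    out.row(t) = a.t();
  }
  if (!out.is_finite())
    Rcpp::stop("non-finite state encountered during iteration");
  return out;
}

// Orthonormalize columns of Q against R from qr_econ, forcing positive
// diagonal so accumulated log|R_ii| are well defined.
static inline void qr_pos(mat& M, mat& Q, mat& R) {
  arma::qr_econ(Q, R, M);
  for (arma::uword i = 0; i < R.n_rows; ++i) {
    if (R(i, i) < 0) { R.row(i) *= -1.0; Q.col(i) *= -1.0; }
  }
}

// Lyapunov spectrum of a single module along the orbit from a0.
// Jacobian at state a is w * diag(1 - tanh(a)^2).
// [[Rcpp::export]]
arma::vec lyap_cpp(const arma::vec& theta, const arma::mat& w,
                   const arma::vec& a0, int n_transient, int n_steps) {
  const arma::uword n = a0.n_elem;
  vec a = a0;
  for (int t = 0; t < n_transient; ++t) a = step_vec(theta, w, a);
  mat Q = arma::eye(n, n), R(n, n), J(n, n);
  vec acc = arma::zeros(n);
  for (int t = 0; t < n_steps; ++t) {
    vec d = 1.0 - arma::square(arma::tanh(a));
    J = w.each_row() % d.t();   // w * diag(d)
    mat M = J * Q;
    qr_pos(M, Q, R);
    vec rd = R.diag();
    if (rd.min() < 0.0)
      Rcpp::stop("tangent space collapsed during QR accumulation; use a shorter re-orthonormalization interval or a different initial state");
    // an exactly singular Jacobian (zero row/column) legitimately sends
    // an exponent to -infinity; clamp so the average stays finite
    acc += arma::log(arma::clamp(rd, 1e-300, arma::datum::inf));
    a = step_vec(theta, w, a);
  }
  vec ex = arma::sort(acc / (double)n_steps, "descend");
  if (!ex.is_finite()) Rcpp::stop("non-finite Lyapunov accumulation");
  return ex;
}

// Synchronization and transversal spectra along the synchronized orbit
// xi(t) of the w+ module: tangent maps w+ * diag(tau'(xi)) and
// w- * diag(tau'(xi)) share the orbit but carry separate QR accumulators.
// [[Rcpp::export]]
Rcpp::List lyap_split_cpp(const arma::vec& theta, const arma::mat& wplus,
                          const arma::mat& wminus, const arma::vec& xi0,
                          int n_transient, int n_steps) {
  const arma::uword n = xi0.n_elem;
  vec xi = xi0;
  for (int t = 0; t < n_transient; ++t) xi = step_vec(theta, wplus, xi);
  mat Qs = arma::eye(n, n), Qt = arma::eye(n, n), R(n, n);
  vec accs = arma::zeros(n), acct = arma::zeros(n);
  for (int t = 0; t < n_steps; ++t) {
    vec d = 1.0 - arma::square(arma::tanh(xi));
    mat Js = wplus.each_row() % d.t();
    mat Jt = wminus.each_row() % d.t();
    mat M = Js * Qs;
    qr_pos(M, Qs, R);
    accs += arma::log(arma::clamp(R.diag().eval(), 1e-300, arma::datum::inf));
    M = Jt * Qt;
    qr_pos(M, Qt, R);
    acct += arma::log(arma::clamp(R.diag().eval(), 1e-300, arma::datum::inf));
    xi = step_vec(theta, wplus, xi);
  }
  return Rcpp::List::create(
    Rcpp::Named("sync") = arma::sort(accs / (double)n_steps, "descend"),
    Rcpp::Named("transversal") = arma::sort(acct / (double)n_steps, "descend"));
}

static inline double sqdist_rows(const mat& X, arma::uword i,
                                 const mat& Y, arma::uword j) {
  double s = 0.0;
  for (arma::uword c = 0; c < X.n_cols; ++c) {
    double d = X(i, c) - Y(j, c);
    s += d * d;
  }
  return s;
}

// Symmetric Hausdorff distance between two point clouds (rows = points).
// [[Rcpp::export]]
double hausdorff_cpp(const arma::mat& X, const arma::mat& Y) {
  double hxy = 0.0, hyx = 0.0;
  arma::vec mins_y(Y.n_rows, arma::fill::value(arma::datum::inf));
  for (arma::uword i = 0; i < X.n_rows; ++i) {
    double best = arma::datum::inf;
    for (arma::uword j = 0; j < Y.n_rows; ++j) {
      double d = sqdist_rows(X, i, Y, j);
      if (d < best) best = d;
      if (d < mins_y(j)) mins_y(j) = d;
    }
    if (best > hxy) hxy = best;
  }
  hyx = mins_y.max();
  double h = hxy > hyx ? hxy : hyx;
  return std::sqrt(h);
}

// Average nearest-neighbour (average Hausdorff) distance between two
// point clouds: mean over each cloud of the distance to the nearest
// point of the other, averaged over both directions.  Far more robust
// to finite sampling of a chaotic set than the max-based Hausdorff
// distance, whose value is dominated by the largest coverage gap.
// [[Rcpp::export]]
double meannn_cpp(const arma::mat& X, const arma::mat& Y) {
  double sx = 0.0, sy = 0.0;
  arma::vec mins_y(Y.n_rows, arma::fill::value(arma::datum::inf));
  for (arma::uword i = 0; i < X.n_rows; ++i) {
    double best = arma::datum::inf;
    for (arma::uword j = 0; j < Y.n_rows; ++j) {
      double d = sqdist_rows(X, i, Y, j);
      if (d < best) best = d;
      if (d < mins_y(j)) mins_y(j) = d;
    }
    sx += std::sqrt(best);
  }
  for (arma::uword j = 0; j < Y.n_rows; ++j) sy += std::sqrt(mins_y(j));
  return 0.5 * (sx / X.n_rows + sy / Y.n_rows);
}

// Fast decision version: is the symmetric Hausdorff distance below
// `thresh`?  Each directed check exits a row as soon as a neighbor
// within thresh is found, and the whole test fails on the first
// uncovered point.
// [[Rcpp::export]]
bool hausdorff_below_cpp(const arma::mat& X, const arma::mat& Y,
                         double thresh) {
  const double t2 = thresh * thresh;
  for (arma::uword i = 0; i < X.n_rows; ++i) {
    bool ok = false;
    for (arma::uword j = 0; j < Y.n_rows; ++j) {
      if (sqdist_rows(X, i, Y, j) < t2) { ok = true; break; }
    }
    if (!ok) return false;
  }
  for (arma::uword j = 0; j < Y.n_rows; ++j) {
    bool ok = false;
    for (arma::uword i = 0; i < X.n_rows; ++i) {
      if (sqdist_rows(X, i, Y, j) < t2) { ok = true; break; }
    }
    if (!ok) return false;
  }
  return true;
}
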