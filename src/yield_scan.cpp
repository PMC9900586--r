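// Compiled kernel for orientation scans of the singlet yield.
//
// Per direction: assemble H = H0 + omega * (b . Z), diagonalize
// (divide-and-conquer Hermitian eigensolver), express the singlet projector
// in the eigenbasis through its rank factor Q, and accumulate the
// Lorentzian-weighted double sum
//   Phi_S = (1/M) sum_{mn} |P_mn|^2 k^2 / (k^2 + (w_m - w_n)^2).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static double lorentzian_sum(const vec& ev, const cx_mat& P,
                             uword M, double k_us) {
  const uword d = ev.n_elem;
  const double k2 = k_us * k_us;
  double acc = 0.0;
  for (uword n = 0; n < d; ++n) {
    const std::complex<double>* col = P.colptr(n);
    const double wn = ev(n);
    for (uword m = 0; m < d; ++m) {
      const double dw = ev(m) - wn;
      acc += std::norm(col[m]) * k2 / (k2 + dw * dw);
    }
  }
  double phi = acc / double(M);
  if (phi < 0.0) phi = 0.0;
  if (phi > 1.0) phi = 1.0;
  return phi;
}

static double yield_from_eigen(const vec& ev, const cx_mat& V,
                               const cx_mat& Q, double k_us) {
  cx_mat W = Q.t() * V;          // M x d (conjugate transpose)
  cx_mat P = W.t() * W;          // P_S in the eigenbasis, d x d
  return lorentzian_sum(ev, P, Q.n_cols, k_us);
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_yield_scan(const arma::cx_mat& H0,
                                   const arma::cx_mat& Zx,
                                   const arma::cx_mat& Zy,
                                   const arma::cx_mat& Zz,
                                   const arma::cx_mat& Q,
                                   const arma::mat& dirs,
                                   double omega, double k_us) {
  const uword n_dir = dirs.n_rows;
  const uword d = H0.n_rows;
  const uword M = Q.n_cols;
  Rcpp::NumericVector out(n_dir);
  vec ev(d);
  cx_mat V(d, d), H(d, d), W(M, d), P(d, d);
  // H0, Zx, Zy, Zz are Hermitian by construction upstream, so each H is
  // Hermitian without re-symmetrization here.
  for (uword i = 0; i < n_dir; ++i) {
    H = H0;
    H += (omega * dirs(i, 0)) * Zx;
    H += (omega * dirs(i, 1)) * Zy;
    H += (omega * dirs(i, 2)) * Zz;
    if (!eig_sym(ev, V, H, "dc"))
      Rcpp::stop("Hermitian eigendecomposition failed");
    W = Q.t() * V;
    P = W.t() * W;
    out[i] = lorentzian_sum(ev, P, M, k_us);
    if (i % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
double cpp_singlet_yield(const arma::cx_mat& H, const arma::cx_mat& Q,
                         double k_us) {
  vec ev;
  cx_mat V;
  cx_mat Hs = (H + H.t()) / 2.0;
  if (!eig_sym(ev, V, Hs, "dc"))
    Rcpp::stop("Hermitian eigendecomposition failed");
  return yield_from_eigen(ev, V, Q, k_us);
}
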