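// Fast evaluation of the spectral-DCM forward model and its numerical
// Jacobian, used by the variational-Laplace inverter. The plain-R forward
// model in R/forward_model.R is the reference implementation; tests assert
// agreement between the two.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// theta layout (matching param_names()): free off-diagonal A entries in
// column-major order over offidx, then self(n), amp(n), exp(n), noise_amp,
// noise_exp, transit(n), decay(n), epsilon.
// consts: gamma, grubb, E0, V0, kappa0, tau0, eps0, k1, k2, k3, noise_ref.

static vec forward_stack(const vec& theta, const int n, const umat& offidx,
                         const vec& freqs, const vec& consts) {
  const int nA = offidx.n_rows;
  mat A(n, n, fill::zeros);
  for (int k = 0; k < nA; ++k) {
    A(offidx(k, 0), offidx(k, 1)) = theta(k);
  }
  int pos = nA;
  const vec self_p = theta.subvec(pos, pos + n - 1); pos += n;
  const vec amp    = theta.subvec(pos, pos + n - 1); pos += n;
  const vec expo   = theta.subvec(pos, pos + n - 1); pos += n;
  const double namp = theta(pos++);
  const double nexp = theta(pos++);
  const vec transit = theta.subvec(pos, pos + n - 1); pos += n;
  const vec decay   = theta.subvec(pos, pos + n - 1); pos += n;
  const double epsv = theta(pos++);
  for (int i = 0; i < n; ++i) A(i, i) = -0.5 * std::exp(self_p(i));

  const double gamma0 = consts(0), grubb = consts(1), E0 = consts(2),
               V0 = consts(3), kappa0 = consts(4), tau0 = consts(5),
               eps0 = consts(6), k1 = consts(7), k2 = consts(8),
               k3 = consts(9), noise_ref = consts(10);
  const double eps = eps0 * std::exp(epsv);
  const double cf = 1.0 + (1.0 - E0) * std::log(1.0 - E0) / E0;
  const double ia = 1.0 / grubb;

  const int nf = freqs.n_elem;
  const int nre = n * (n + 1) / 2, nim = n * (n - 1) / 2;
  vec out(nf * (nre + nim));

  const cx_mat I_n(n, n, fill::eye);
  const cx_mat Ac(A, mat(n, n, fill::zeros));
  const vec kap = kappa0 * exp(decay);
  const vec tau = tau0 * exp(transit);

  for (int f = 0; f < nf; ++f) {
    const double w = 2.0 * datum::pi * freqs(f);
    const cx_double iw(0.0, w);
    cx_mat T = solve(iw * I_n - Ac, I_n);
    // closed-form transfer of the linearized balloon chain
    cx_vec K(n);
    for (int j = 0; j < n; ++j) {
      const cx_double s_u = 1.0 / (iw + kap(j) + gamma0 / iw);
      const cx_double f_u = s_u / iw;
      const cx_double v_u = f_u / (iw * tau(j) + ia);
      const cx_double q_u = (cf * f_u - (ia - 1.0) * v_u) / (iw * tau(j) + 1.0);
      K(j) = V0 * ((eps * k2 - k3) * v_u - (k1 + eps * k2) * q_u);
    }
    vec gv(n), ge(n);
    for (int j = 0; j < n; ++j) {
      gv(j) = std::exp(amp(j)) * std::pow(w, -expo(j));
      ge(j) = noise_ref * std::exp(namp) * std::pow(w, -nexp);
    }
    cx_mat KS = T;
    for (int i = 0; i < n; ++i) KS.row(i) *= K(i);
    cx_mat G = KS * diagmat(cx_vec(gv, vec(n, fill::zeros))) * KS.t();
    G = 0.5 * (G + G.t());
    for (int j = 0; j < n; ++j) G(j, j) = cx_double(G(j, j).real() + ge(j), 0.0);

    int o = f * (nre + nim);
    for (int j = 0; j < n; ++j) {
      for (int i = 0; i <= j; ++i) out(o++) = G(i, j).real();
    }
    for (int j = 0; j < n; ++j) {
      for (int i = 0; i < j; ++i) out(o++) = G(i, j).imag();
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::vec csd_forward_cpp(const arma::vec& theta, const int n,
                          const arma::umat& offidx, const arma::vec& freqs,
                          const arma::vec& consts) {
  return forward_stack(theta, n, offidx, freqs, consts);
}

// Central-difference Jacobian of the stacked forward prediction.
// [[Rcpp::export]]
Rcpp::List csd_jacobian_cpp(const arma::vec& theta, const int n,
                            const arma::umat& offidx, const arma::vec& freqs,
                            const arma::vec& consts, const double h) {
  const vec g0 = forward_stack(theta, n, offidx, freqs, consts);
  const int p = theta.n_elem;
  mat J(g0.n_elem, p);
  vec tp = theta;
  for (int k = 0; k < p; ++k) {
    tp(k) = theta(k) + h;
    const vec gp = forward_stack(tp, n, offidx, freqs, consts);
    tp(k) = theta(k) - h;
    const vec gm = forward_stack(tp, n, offidx, freqs, consts);
    tp(k) = theta(k);
    J.col(k) = (gp - gm) / (2.0 * h);
  }
  return Rcpp::List::create(Rcpp::Named("g") = g0, Rcpp::Named("J") = J);
}
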