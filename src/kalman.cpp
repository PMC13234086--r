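// Kalman filter + RTS smoother for the latent chain of the dynamic
// coupling-tuning-latent model, state-space form:
//   z_t = G z_{t-1} + eta_t,  eta_t ~ N(0, I_K),  z_1 ~ N(0, I_K)
//   r_t = L z_t + psi_t,      psi_t ~ N(0, diag(Sigma))
// Returns smoothed means, smoothed covariances, lag-one smoothed
// cross-covariances Cov(z_t, z_{t+1}), and the observed-data log-likelihood.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export(name = ".kalman_smoother_cpp")]]
Rcpp::List kalman_smoother_cpp(const arma::mat& R,     // n x N residuals
                               const arma::mat& L,     // N x K
                               const arma::vec& Sigma, // N private variances
                               const arma::mat& G) {   // K x K
  const arma::uword n = R.n_rows, N = R.n_cols, K = L.n_cols;
  arma::mat m_f(K, n), m_p(K, n);
  arma::cube P_f(K, K, n), P_p(K, K, n);
  arma::vec mp(K, arma::fill::zeros);
  arma::mat Pp(K, K, arma::fill::eye);
  const arma::mat IK = arma::eye(K, K);
  const arma::mat SigD = arma::diagmat(Sigma);
  double ll = 0.0;
  const double l2pi = std::log(2.0 * arma::datum::pi);
  for (arma::uword t = 0; t < n; ++t) {
    arma::mat S = L * Pp * L.t() + SigD;
    S = 0.5 * (S + S.t());
    arma::mat Sc = arma::chol(S, "lower");
    arma::vec v = R.row(t).t() - L * mp;
    arma::vec w = arma::solve(arma::trimatl(Sc), v);
    ll += -0.5 * (N * l2pi + 2.0 * arma::accu(arma::log(Sc.diag())) +
                  arma::dot(w, w));
    arma::mat Kg = Pp * L.t() *
      arma::solve(arma::trimatu(Sc.t()), arma::solve(arma::trimatl(Sc),
                  arma::eye(N, N)));
    arma::vec mf = mp + Kg * v;
    arma::mat Pf = (IK - Kg * L) * Pp;
    Pf = 0.5 * (Pf + Pf.t());
    m_p.col(t) = mp; P_p.slice(t) = Pp;
    m_f.col(t) = mf; P_f.slice(t) = Pf;
    mp = G * mf;
    Pp = G * Pf * G.t() + IK;
  }
  arma::mat mu = m_f;
  arma::cube V = P_f;
  arma::cube C(K, K, n > 1 ? n - 1 : 0);
  for (arma::uword t = n - 1; t-- > 0;) {
    arma::mat J = P_f.slice(t) * G.t() * arma::inv_sympd(P_p.slice(t + 1));
    mu.col(t) = m_f.col(t) + J * (mu.col(t + 1) - m_p.col(t + 1));
    arma::mat Vt = P_f.slice(t) +
      J * (V.slice(t + 1) - P_p.slice(t + 1)) * J.t();
    V.slice(t) = 0.5 * (Vt + Vt.t());
    C.slice(t) = J * V.slice(t + 1);
  }
  return Rcpp::List::create(Rcpp::Named("mu") = mu.t(),
                            Rcpp::Named("V") = V,
                            Rcpp::Named("C") = C,
                            Rcpp::Named("loglik") = ll);
}
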