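#include <Rcpp.h>
using namespace Rcpp;

// Marginal negative log-likelihood of a binomial-logit model with a scalar
// N(0, sigma^2) random intercept per observation (one binomial row per
// individual, the random effect absorbing overdispersion).
//
//   y_i ~ Binomial(n_i, p_i),  logit(p_i) = x_i' beta + u_i,  u_i ~ N(0, s^2)
//
// The per-individual integral is evaluated by Gauss-Hermite quadrature:
//   L_i = (1/sqrt(pi)) * sum_k w_k * Binom(y_i | n_i, plogis(eta_i + sqrt(2) s t_k))
// with (t_k, w_k) the physicists' Gauss-Hermite nodes/weights passed in.
//
// par = (beta_1..beta_p, log sigma); X is n x p.

static inline double softplus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// [[Rcpp::export]]
double binom_olre_nll(NumericVector par, NumericVector y, NumericVector n,
                      NumericMatrix X, NumericVector gh_nodes,
                      NumericVector gh_weights) {
  const int N = y.size();
  const int P = X.ncol();
  if (par.size() != P + 1) stop("par must have length ncol(X) + 1");
  const int K = gh_nodes.size();
  if (K > 64) stop("at most 64 quadrature nodes supported");
  const double sigma = std::exp(par[P]);
  const double sqrt2s = M_SQRT2 * sigma;
  const double log_sqrt_pi = 0.5 * std::log(M_PI);

  std::vector<double> logw(K);
  for (int k = 0; k < K; ++k) logw[k] = std::log(gh_weights[k]) - log_sqrt_pi;

  double nll = 0.0;
  for (int i = 0; i < N; ++i) {
    double eta0 = 0.0;
    for (int j = 0; j < P; ++j) eta0 += X(i, j) * par[j];
    double m = R_NegInf;
    double terms[64];
    for (int k = 0; k < K; ++k) {
      const double eta = eta0 + sqrt2s * gh_nodes[k];
      // log Binom kernel without the constant choose(n, y) term
      const double ll = y[i] * eta - n[i] * softplus(eta);
      const double t = logw[k] + ll;
      terms[k] = t;
      if (t > m) m = t;
    }
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += std::exp(terms[k] - m);
    nll -= m + std::log(s);
  }
  return nll;
}

// Gradient of binom_olre_nll with respect to (beta, log sigma). Uses the
// posterior quadrature weights: d nll / d beta_j =
//   -sum_i sum_k wpost_ik (y_i - n_i p_ik) x_ij, and the log-sigma component
// replaces x_ij by sqrt(2) sigma t_k.
// [[Rcpp::export]]
NumericVector binom_olre_grad(NumericVector par, NumericVector y,
                              NumericVector n, NumericMatrix X,
                              NumericVector gh_nodes,
                              NumericVector gh_weights) {
  const int N = y.size();
  const int P = X.ncol();
  const int K = gh_nodes.size();
  if (K > 64) stop("at most 64 quadrature nodes supported");
  const double sigma = std::exp(par[P]);
  const double sqrt2s = M_SQRT2 * sigma;

  NumericVector grad(P + 1);
  double terms[64], resid[64];
  for (int i = 0; i < N; ++i) {
    double eta0 = 0.0;
    for (int j = 0; j < P; ++j) eta0 += X(i, j) * par[j];
    double m = R_NegInf;
    for (int k = 0; k < K; ++k) {
      const double eta = eta0 + sqrt2s * gh_nodes[k];
      const double p = 1.0 / (1.0 + std::exp(-eta));
      resid[k] = y[i] - n[i] * p;
      const double t = std::log(gh_weights[k]) + y[i] * eta - n[i] * softplus(eta);
      terms[k] = t;
      if (t > m) m = t;
    }
    double s = 0.0;
    for (int k = 0; k < K; ++k) { terms[k] = std::exp(terms[k] - m); s += terms[k]; }
    double gb = 0.0, gs = 0.0;
    for (int k = 0; k < K; ++k) {
      const double w = terms[k] / s;
      gb += w * resid[k];
      gs += w * resid[k] * sqrt2s * gh_nodes[k];
    }
    for (int j = 0; j < P; ++j) grad[j] -= gb * X(i, j);
    grad[P] -= gs;
  }
  return grad;
}

// Log binomial coefficient sum: the constant part of the log-likelihood,
// so callers can report full log-likelihoods comparable across software.
// [[Rcpp::export]]
double binom_lchoose_sum(NumericVector y, NumericVector n) {
  double s = 0.0;
  for (int i = 0; i < y.size(); ++i) s += Rf_lchoose(n[i], y[i]);
  return s;
}
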