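#' @useDynLib prefqtl, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Cache Gauss-Hermite rules so repeated scan fits do not recompute them.
.gh_cache <- new.env(parent = emptyenv())

gh_rule <- function(n_nodes) {
  key <- as.character(n_nodes)
  if (is.null(.gh_cache[[key]])) {
    .gh_cache[[key]] <- pracma::gaussHermite(n_nodes)
  }
  .gh_cache[[key]]
}

#' Fit a binomial-logit model with an individual-level random intercept
#'
#' Maximum-likelihood fit of
#' \deqn{y_i \sim \mathrm{Binomial}(n_i, p_i), \quad
#'       \mathrm{logit}(p_i) = x_i'\beta + u_i, \quad u_i \sim N(0, \sigma^2)}
#' with one binomial row per individual, so the scalar random intercept acts
#' as an observation-level effect absorbing overdispersion relative to the
#' binomial. The marginal likelihood integrates \eqn{u_i} out by Gauss-Hermite
#' quadrature (default 21 nodes); optimization is over
#' \eqn{(\beta, \log\sigma)} with a BFGS start refined by Nelder-Mead when the
#' first pass fails to converge.
#'
#' @param y successes per individual (e.g. courtship minutes toward
#'   *H. melpomene*).
#' @param n trials per individual (total courtship minutes); must satisfy
#'   `n >= y`.
#' @param X fixed-effect design matrix (include the intercept column
#'   yourself); defaults to intercept-only.
#' @param start optional starting values `c(beta, log_sigma)`.
#' @param n_nodes number of quadrature nodes (>= 15 recommended).
#' @param reltol convergence tolerance passed to [stats::optim()].
#' @return list with `coef` (named vector), `sigma`, `loglik` (full binomial
#'   log-likelihood including the constant term), `converged`, `par`.
#' @export
fit_binom_olre <- function(y, n, X = NULL, start = NULL, n_nodes = 21,
                           reltol = 1e-10) {
  y <- as.numeric(y)
  n <- as.numeric(n)
  if (length(y) != length(n)) stop("y and n must have equal length")
  if (any(y < 0) || any(n < y)) stop("need 0 <= y <= n")
  if (is.null(X)) X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) != length(y)) stop("nrow(X) must match length(y)")
  gh <- gh_rule(n_nodes)
  p <- ncol(X)

  if (is.null(start)) {
    # moment start: quasibinomial GLM for beta, residual deviance for sigma
    fit0 <- suppressWarnings(stats::glm.fit(X, cbind(y, n - y),
                                            family = stats::binomial()))
    start <- c(fit0$coefficients, log(0.5))
    start[!is.finite(start)] <- 0
  }

  nll <- function(par) {
    v <- binom_olre_nll(par, y, n, X, gh$x, gh$w)
    if (!is.finite(v)) 1e10 else v
  }
  gr <- function(par) binom_olre_grad(par, y, n, X, gh$x, gh$w)
  opt <- stats::optim(start, nll, gr, method = "BFGS",
                      control = list(reltol = reltol, maxit = 500))
  if (opt$convergence != 0) {
    opt2 <- stats::optim(opt$par, nll, method = "Nelder-Mead",
                         control = list(reltol = reltol, maxit = 2000))
    if (opt2$value <= opt$value) opt <- opt2
  }
  cf <- opt$par[seq_len(p)]
  names(cf) <- colnames(X)
  list(coef = cf,
       sigma = unname(exp(opt$par[p + 1])),
       loglik = -opt$value + binom_lchoose_sum(y, n),
       converged = opt$convergence == 0,
       par = opt$par)
}

#' Fit the fixed-effects-only binomial model (random intercept pinned to zero)
#'
#' Ordinary binomial GLM via [stats::glm.fit()]; used for oracle comparisons
#' and for the `sigma = 0` degenerate case of [fit_binom_olre()].
#'
#' @inheritParams fit_binom_olre
#' @return list with `coef`, `sigma = 0`, `loglik`, `converged`.
#' @export
fit_binom_fixed <- function(y, n, X = NULL) {
  y <- as.numeric(y); n <- as.numeric(n)
  if (is.null(X)) X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  fit <- suppressWarnings(stats::glm.fit(X, cbind(y, n - y),
                                         family = stats::binomial()))
  eta <- drop(X %*% fit$coefficients)
  ll <- sum(stats::dbinom(y, n, stats::plogis(eta), log = TRUE))
  list(coef = stats::setNames(fit$coefficients, colnames(X)),
       sigma = 0, loglik = ll, converged = fit$converged)
}

# Likelihood-ratio comparison of two nested fits from the fitters above.
lrt_fits <- function(fit_full, fit_null, df) {
  stat <- max(0, 2 * (fit_full$loglik - fit_null$loglik))
  list(stat = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}
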