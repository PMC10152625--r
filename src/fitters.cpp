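// Newton/IRLS cores for logistic regression: plain maximum likelihood,
// ridge-penalized likelihood (quadratic penalty, intercept unpenalized),
// and Firth's Jeffreys-prior penalized likelihood.  Kept in compiled code
// because the resampling techniques refit these models thousands of times.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// unpenalized binomial log-likelihood, numerically stable in eta
static double binll(const vec& y, const vec& eta) {
  double s = 0.0;
  for (uword i = 0; i < y.n_elem; ++i) {
    double e = eta[i];
    double l1p = (e > 30.0) ? e : std::log1p(std::exp(e));
    s += y[i] * e - l1p;
  }
  return s;
}

static vec expit(const vec& eta) { return 1.0 / (1.0 + exp(-eta)); }

// Newton with step-halving for l(beta) - 0.5 * sum(pendiag * beta^2).
// pendiag = 2 * lambda * s_j^2 (0 for the intercept) gives the penalty
// lambda * sum((s_j beta_j)^2), i.e. a squared-norm penalty on the
// standardized slope scale.
// [[Rcpp::export(name = ".irls_fit")]]
Rcpp::List irls_fit(const arma::mat& X, const arma::vec& y,
                    const arma::vec& pendiag, const arma::vec& start,
                    int maxit, double tol) {
  const uword p = X.n_cols;
  vec beta = start;
  vec eta = X * beta;
  double pl = binll(y, eta) - 0.5 * dot(pendiag, beta % beta);
  bool converged = false;
  int it = 0;
  for (it = 0; it < maxit; ++it) {
    vec prob = expit(eta);
    vec w = prob % (1.0 - prob);
    mat H = X.t() * (X.each_col() % w);
    H.diag() += pendiag;
    vec g = X.t() * (y - prob) - pendiag % beta;
    vec step;
    bool ok = solve(step, H, g, solve_opts::no_approx);
    if (!ok) {
      H.diag() += 1e-8;  // near-singular information (e.g. separation)
      if (!solve(step, H, g, solve_opts::no_approx)) break;
    }
    double delta = norm(step, "inf");
    // step-halving on the penalized objective
    double fac = 1.0;
    vec beta_new, eta_new;
    double pl_new = -datum::inf;
    for (int h = 0; h < 16; ++h) {
      beta_new = beta + fac * step;
      eta_new = X * beta_new;
      pl_new = binll(y, eta_new) - 0.5 * dot(pendiag, beta_new % beta_new);
      if (pl_new >= pl - 1e-12) break;
      fac *= 0.5;
    }
    beta = beta_new; eta = eta_new; pl = pl_new;
    if (delta * fac < tol || delta < tol) { converged = true; ++it; break; }
  }
  return Rcpp::List::create(
    Rcpp::Named("beta") = beta,
    Rcpp::Named("loglik") = binll(y, eta),
    Rcpp::Named("converged") = converged,
    Rcpp::Named("iter") = it,
    Rcpp::Named("max_abs_eta") = eta.n_elem ? norm(eta, "inf") : 0.0);
  (void)p;
}

// Firth's modified-score fit: maximizes l(beta) + 0.5 log det I(beta).
// [[Rcpp::export(name = ".firth_fit")]]
Rcpp::List firth_fit(const arma::mat& X, const arma::vec& y,
                     const arma::vec& start, int maxit, double tol) {
  vec beta = start;
  vec eta = X * beta;
  bool converged = false;
  int it = 0;
  double ld;
  {
    vec prob = expit(eta);
    vec w = clamp(prob % (1.0 - prob), 1e-12, datum::inf);
    mat I = X.t() * (X.each_col() % w);
    double sign; log_det(ld, sign, I);
  }
  double pl = binll(y, eta) + 0.5 * ld;
  for (it = 0; it < maxit; ++it) {
    vec prob = expit(eta);
    vec w = clamp(prob % (1.0 - prob), 1e-12, datum::inf);
    mat I = X.t() * (X.each_col() % w);
    mat Iinv;
    if (!inv_sympd(Iinv, I)) {
      if (!inv(Iinv, I)) break;
    }
    // hat diagonal h_i = w_i x_i' I^{-1} x_i
    vec h(X.n_rows);
    for (uword i = 0; i < X.n_rows; ++i) {
      rowvec xi = X.row(i);
      h[i] = w[i] * as_scalar(xi * Iinv * xi.t());
    }
    vec U = X.t() * (y - prob + h % (0.5 - prob));
    vec step = Iinv * U;
    double delta = norm(step, "inf");
    double fac = 1.0;
    vec beta_new, eta_new;
    double pl_new = -datum::inf;
    for (int hh = 0; hh < 16; ++hh) {
      beta_new = beta + fac * step;
      eta_new = X * beta_new;
      vec pn = expit(eta_new);
      vec wn = clamp(pn % (1.0 - pn), 1e-12, datum::inf);
      mat In = X.t() * (X.each_col() % wn);
      double ldn, sign; log_det(ldn, sign, In);
      pl_new = binll(y, eta_new) + 0.5 * ldn;
      if (pl_new >= pl - 1e-12) break;
      fac *= 0.5;
    }
    beta = beta_new; eta = eta_new; pl = pl_new;
    if (delta * fac < tol || delta < tol) { converged = true; ++it; break; }
  }
  return Rcpp::List::create(
    Rcpp::Named("beta") = beta,
    Rcpp::Named("loglik") = binll(y, eta),
    Rcpp::Named("penloglik") = pl,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("iter") = it);
}

// Ridge path over a lambda grid with warm starts (fitted from the largest
// lambda down).  s2pen holds the squared standardization scales (0 for the
// intercept); the penalty at lambda is lambda * sum(s2pen * beta^2).
// Returns per-lambda coefficients, unpenalized log-likelihood, effective
// degrees of freedom trace(I (I + 2 lambda S)^(-1)), and convergence flags,
// in the order of the supplied grid.
// [[Rcpp::export(name = ".ridge_path")]]
Rcpp::List ridge_path(const arma::mat& X, const arma::vec& y,
                      const arma::vec& s2pen, const arma::vec& lambdas,
                      int maxit, double tol) {
  const uword p = X.n_cols, m = lambdas.n_elem;
  uvec ord = sort_index(lambdas, "descend");
  mat betas(p, m, fill::zeros);
  vec ll(m), dfe(m);
  ivec conv(m);
  vec warm(p, fill::zeros);
  for (uword k = 0; k < m; ++k) {
    uword j = ord[k];
    vec pendiag = 2.0 * lambdas[j] * s2pen;
    Rcpp::List fit = irls_fit(X, y, pendiag, warm, maxit, tol);
    vec beta = Rcpp::as<vec>(fit["beta"]);
    warm = beta;
    betas.col(j) = beta;
    ll[j] = Rcpp::as<double>(fit["loglik"]);
    conv[j] = Rcpp::as<bool>(fit["converged"]) ? 1 : 0;
    // effective degrees of freedom
    vec prob = expit(X * beta);
    vec w = prob % (1.0 - prob);
    mat I = X.t() * (X.each_col() % w);
    mat Ipen = I; Ipen.diag() += pendiag;
    mat ratio;
    if (solve(ratio, Ipen, I, solve_opts::no_approx))
      dfe[j] = trace(ratio);
    else
      dfe[j] = (double)p;
  }
  return Rcpp::List::create(
    Rcpp::Named("beta") = betas,
    Rcpp::Named("loglik") = ll,
    Rcpp::Named("df_e") = dfe,
    Rcpp::Named("converged") = conv);
}
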