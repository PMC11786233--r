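// Iteratively reweighted least squares for unpenalized logistic regression.
// Used thousands of times inside bootstrap replicates, where glm.fit's
// per-call overhead dominates; supports warm starts from the full-data fit
// so resample refits converge in a couple of iterations. A tiny ridge keeps
// the normal equations well-posed when a resample leaves a column constant.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".irls_logistic")]]
Rcpp::List irls_logistic(const arma::mat& X, const arma::vec& y,
                         const arma::vec& start, int maxit = 50,
                         double tol = 1e-9, double ridge = 1e-8) {
  const uword p = X.n_cols;
  vec beta = start;
  if (beta.n_elem != p) beta = zeros<vec>(p);
  mat R = ridge * eye<mat>(p, p);
  double dev_old = datum::inf;
  bool converged = false;

  for (int it = 0; it < maxit; ++it) {
    vec eta = clamp(X * beta, -30.0, 30.0);
    vec mu = 1.0 / (1.0 + exp(-eta));
    vec w = mu % (1.0 - mu);
    w = clamp(w, 1e-10, 0.25);
    vec z = eta + (y - mu) / w;
    mat Xw = X.each_col() % w;
    mat A = X.t() * Xw + R;
    vec b = Xw.t() * z;
    vec beta_new;
    if (!solve(beta_new, A, b, solve_opts::likely_sympd)) {
      solve(beta_new, A + 1e-4 * eye<mat>(p, p), b);
    }
    beta = beta_new;
    vec eta2 = clamp(X * beta, -30.0, 30.0);
    vec mu2 = 1.0 / (1.0 + exp(-eta2));
    mu2 = clamp(mu2, 1e-12, 1.0 - 1e-12);
    double dev = -2.0 * accu(y % log(mu2) + (1.0 - y) % log(1.0 - mu2));
    if (std::abs(dev - dev_old) < tol * (std::abs(dev) + 0.1)) {
      converged = true;
      break;
    }
    dev_old = dev;
  }
  return Rcpp::List::create(Rcpp::Named("beta") = beta,
                            Rcpp::Named("converged") = converged);
}
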