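#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Weighted logistic regression by iteratively reweighted least squares.
// y may be fractional (aggregated event proportions); w are prior weights
// (case weights, IP weights, or binomial denominators). Linearly dependent
// columns are handled through a pseudo-inverse fall-back.
// [[Rcpp::export(name = ".irls_logistic")]]
Rcpp::List irls_logistic(const arma::mat& X,
                         const arma::vec& y,
                         const arma::vec& w,
                         const int max_iter = 50,
                         const double tol = 1e-10) {
  const uword p = X.n_cols;
  vec beta(p, fill::zeros);
  vec eta(X.n_rows, fill::zeros);
  double dev_old = datum::inf;
  bool converged = false;

  for (int it = 0; it < max_iter; ++it) {
    vec mu = 1.0 / (1.0 + exp(-eta));
    // keep fitted values away from 0/1 so the working weights stay finite
    mu = clamp(mu, 1e-12, 1.0 - 1e-12);
    vec wt = w % mu % (1.0 - mu);
    vec z = eta + (y - mu) / (mu % (1.0 - mu));
    mat Xw = X.each_col() % wt;
    mat XtWX = X.t() * Xw;
    vec XtWz = Xw.t() * z;
    vec beta_new;
    bool ok = solve(beta_new, XtWX, XtWz, solve_opts::no_approx);
    if (!ok) beta_new = pinv(XtWX) * XtWz;
    eta = X * beta_new;
    eta = clamp(eta, -30.0, 30.0);
    beta = beta_new;

    vec mu2 = clamp(1.0 / (1.0 + exp(-eta)), 1e-12, 1.0 - 1e-12);
    double dev = -2.0 * accu(w % (y % log(mu2) + (1.0 - y) % log(1.0 - mu2)));
    if (std::abs(dev - dev_old) < tol * (std::abs(dev) + 0.1)) {
      converged = true;
      break;
    }
    dev_old = dev;
  }

  vec fitted = 1.0 / (1.0 + exp(-(X * beta)));
  return Rcpp::List::create(
      Rcpp::Named("coefficients") = beta,
      Rcpp::Named("fitted") = fitted,
      Rcpp::Named("converged") = converged);
}
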