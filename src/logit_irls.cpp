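// Weighted-least-squares IRLS for logistic regression on a dense model
// matrix. Used on the hot paths (bootstrap replicates, recovery and
// calibration experiments) where the formula/model.frame machinery of
// glm() dominates runtime. Inference-quality fits go through glm()/glmer();
// this solver only needs coefficients and fitted probabilities.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double binom_deviance(const arma::vec& y, const arma::vec& mu) {
  // -2 log-likelihood; y is 0/1 so only one branch contributes per row
  arma::vec ll = y % arma::log(mu) + (1.0 - y) % arma::log(1.0 - mu);
  return -2.0 * arma::accu(ll);
}

// [[Rcpp::export(name = ".logit_irls")]]
List logit_irls(const arma::mat& X, const arma::vec& y,
                const double tol = 1e-8, const int max_iter = 100,
                Rcpp::Nullable<Rcpp::NumericVector> init = R_NilValue) {
  const arma::uword p = X.n_cols;
  arma::vec beta(p, arma::fill::zeros);
  if (init.isNotNull() && Rcpp::NumericVector(init).size() == (int) p) {
    beta = Rcpp::as<arma::vec>(init);   // warm start (bootstrap replicates)
  } else {
    // intercept warm start when first column is constant 1
    double ybar = arma::mean(y);
    ybar = std::min(std::max(ybar, 1e-10), 1.0 - 1e-10);
    if (arma::all(X.col(0) == 1.0)) beta(0) = std::log(ybar / (1.0 - ybar));
  }

  arma::vec eta = X * beta;
  arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
  mu = arma::clamp(mu, 1e-10, 1.0 - 1e-10);
  double dev = binom_deviance(y, mu);
  bool converged = false;
  int iter = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    arma::vec w = mu % (1.0 - mu);          // working weights
    w = arma::clamp(w, 1e-10, 0.25);
    arma::vec z = eta + (y - mu) / w;       // working response
    arma::mat Xw = X.each_col() % w;
    arma::mat XtWX = X.t() * Xw;
    arma::vec XtWz = Xw.t() * z;
    arma::vec beta_new;
    bool ok = arma::solve(beta_new, XtWX, XtWz,
                          arma::solve_opts::likely_sympd + arma::solve_opts::no_approx);
    if (!ok) {
      return List::create(_["coefficients"] = beta, _["fitted"] = mu,
                          _["converged"] = false, _["iterations"] = iter,
                          _["deviance"] = dev, _["singular"] = true);
    }
    // step-halving if deviance does not improve (guards near-separation)
    arma::vec step = beta_new - beta;
    double dev_new = R_PosInf;
    arma::vec eta_new, mu_new;
    for (int h = 0; h < 30; ++h) {
      eta_new = X * (beta + step);
      mu_new = arma::clamp(1.0 / (1.0 + arma::exp(-eta_new)), 1e-10, 1.0 - 1e-10);
      dev_new = binom_deviance(y, mu_new);
      if (std::isfinite(dev_new) && dev_new <= dev * (1.0 + 1e-12) + 1e-12) break;
      step *= 0.5;
    }
    beta += step;
    eta = eta_new;
    mu = mu_new;
    if (std::abs(dev - dev_new) / (std::abs(dev_new) + 0.1) < tol) {
      dev = dev_new;
      converged = true;
      break;
    }
    dev = dev_new;
  }

  return List::create(_["coefficients"] = beta, _["fitted"] = mu,
                      _["converged"] = converged, _["iterations"] = iter,
                      _["deviance"] = dev, _["singular"] = false);
}

// Ordinary least squares via normal equations with a QR fallback; returns
// coefficients only (bootstrap hot path for the linear robustness models).
// [[Rcpp::export(name = ".ols_coef")]]
arma::vec ols_coef(const arma::mat& X, const arma::vec& y) {
  arma::vec beta;
  if (!arma::solve(beta, X.t() * X, X.t() * y,
                   arma::solve_opts::likely_sympd + arma::solve_opts::no_approx)) {
    arma::solve(beta, X, y);
  }
  return beta;
}
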