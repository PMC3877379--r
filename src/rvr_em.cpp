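// Sparse Bayesian regression core: evidence maximization with basis pruning.
// Kept in C++ because recursive feature elimination refits this model
// hundreds of times per cross-validation split. The Gram products Phi'Phi
// and Phi'y are cached and subset on pruning rather than recomputed.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// posterior at fixed hyperparameters from cached Gram products
void posterior(const arma::mat& PtP, const arma::vec& Pty,
               const arma::vec& alpha, double sigma2,
               arma::mat& Sigma, arma::vec& mu) {
  arma::mat H = PtP / sigma2;
  H.diag() += alpha + 1e-10;
  if (!arma::inv_sympd(Sigma, H)) {
    H.diag() += 1e-6;
    Sigma = arma::inv(H);
  }
  mu = Sigma * Pty / sigma2;
}

} // namespace

// Iterate the standard sparse-Bayesian updates on a fixed design matrix Phi:
//   Sigma = (diag(alpha) + Phi'Phi / sigma2)^-1
//   mu    = Sigma Phi' y / sigma2
//   g_i   = 1 - alpha_i Sigma_ii
//   alpha_i <- g_i / mu_i^2
//   sigma2  <- ||y - Phi mu||^2 / (n - sum g)
// Basis functions with alpha above alpha_prune are removed from the active
// set. Convergence: max |delta log alpha| < tol over the surviving set.
// [[Rcpp::export(name = ".rvr_em_cpp")]]
List rvr_em_cpp(const arma::mat& Phi, const arma::vec& y,
                arma::vec alpha, double sigma2,
                double tol, int max_iter, double alpha_prune,
                bool update_alpha, bool update_sigma2) {
  const arma::uword n = Phi.n_rows;
  const arma::uword M = Phi.n_cols;

  arma::uvec active = arma::regspace<arma::uvec>(0, M - 1);
  arma::vec alpha_act = alpha;
  arma::vec mu;
  arma::mat Sigma;
  bool converged = false;
  int iters = 0;
  std::vector<double> logev;

  arma::mat PtP = Phi.t() * Phi;
  arma::vec Pty = Phi.t() * y;
  const double yty = arma::dot(y, y);

  for (int it = 0; it < max_iter; ++it) {
    iters = it + 1;
    if (active.n_elem == 0) break;

    posterior(PtP, Pty, alpha_act, sigma2, Sigma, mu);
    arma::vec g = 1.0 - alpha_act % Sigma.diag();

    // log marginal likelihood via the Woodbury identities:
    // log|C| = n log sigma2 - log|Sigma| + sum log(1/alpha)
    // y'C^-1 y = (y'y - y'Phi mu) / sigma2
    double val, sign;
    arma::log_det(val, sign, Sigma);
    double logdetC = n * std::log(sigma2) - val - arma::accu(arma::log(alpha_act));
    double quad = (yty - arma::dot(Pty, mu)) / sigma2;
    logev.push_back(-0.5 * (n * std::log(2.0 * M_PI) + logdetC + quad));

    if (!update_alpha && !update_sigma2) { converged = true; break; }

    arma::vec alpha_new = alpha_act;
    if (update_alpha) {
      for (arma::uword i = 0; i < active.n_elem; ++i) {
        double mi2 = mu(i) * mu(i);
        alpha_new(i) = (mi2 > 0.0) ? std::max(g(i), 1e-12) / mi2 : 2.0 * alpha_prune;
      }
    }
    if (update_sigma2) {
      double rss = yty - 2.0 * arma::dot(mu, Pty) +
        arma::as_scalar(mu.t() * PtP * mu);
      if (rss < 0.0) rss = 0.0;
      double denom = static_cast<double>(n) - arma::accu(g);
      if (denom < 1e-6) denom = 1e-6;
      sigma2 = std::max(rss / denom, 1e-12);
    }

    arma::uvec keep = arma::find(alpha_new <= alpha_prune);
    double max_dlog = 0.0;
    if (update_alpha) {
      for (arma::uword j = 0; j < keep.n_elem; ++j) {
        arma::uword i = keep(j);
        double d = std::fabs(std::log(alpha_new(i)) - std::log(alpha_act(i)));
        if (d > max_dlog) max_dlog = d;
      }
    }

    bool pruned = keep.n_elem < active.n_elem;
    if (pruned) {
      active = active.elem(keep);
      alpha_act = alpha_new.elem(keep);
      PtP = PtP.submat(keep, keep);
      Pty = Pty.elem(keep);
    } else {
      alpha_act = alpha_new;
    }

    if (active.n_elem == 0) break;
    if (update_alpha && !pruned && max_dlog < tol) {
      posterior(PtP, Pty, alpha_act, sigma2, Sigma, mu);
      converged = true;
      break;
    }
    if (pruned) posterior(PtP, Pty, alpha_act, sigma2, Sigma, mu);
  }

  if (active.n_elem == 0) {
    mu.reset();
    Sigma.reset();
    alpha_act.reset();
  }
  return List::create(
    _["active"]    = IntegerVector(active.begin(), active.end()),  // 0-based
    _["mu"]        = NumericVector(mu.begin(), mu.end()),
    _["alpha"]     = NumericVector(alpha_act.begin(), alpha_act.end()),
    _["Sigma"]     = Sigma,
    _["sigma2"]    = sigma2,
    _["iterations"] = iters,
    _["converged"] = converged,
    _["logEvidence"] = NumericVector(logev.begin(), logev.end()));
}
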