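// EM estimation for constrained latent class (cognitive diagnosis) models.
//
// The latent space is the 2^K attribute profiles; each item j partitions it
// into latent response groups (2 groups for DINA, 2^{K*_j} for the saturated
// G-DINA), encoded by a J x L group-index matrix. Both models therefore share
// one EM: the E-step computes profile posteriors under the current success
// probabilities and latent distribution, the M-step is the closed-form
// posterior-weighted proportion correct per latent group per item.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LIK_CLAMP = 1e-10; // likelihood-evaluation clamp only

// E-step work: fills post (N x L) and returns the marginal log-likelihood
static double e_step_ll(const arma::mat& X, const arma::mat& P,
                        const arma::vec& pi, arma::mat& post) {
  const arma::uword N = X.n_rows, L = P.n_cols;
  arma::mat Pc = arma::clamp(P, LIK_CLAMP, 1.0 - LIK_CLAMP);
  arma::mat logP = arma::log(Pc), log1mP = arma::log(1.0 - Pc);
  arma::mat A = logP - log1mP;                 // J x L
  arma::rowvec b = arma::sum(log1mP, 0);       // 1 x L
  arma::mat LL = X * A;                        // N x L
  LL.each_row() += b;
  arma::rowvec logpi(L);
  for (arma::uword l = 0; l < L; ++l)
    logpi(l) = pi(l) > 0 ? std::log(pi(l)) : -arma::datum::inf;
  LL.each_row() += logpi;
  double ll = 0.0;
  post.set_size(N, L);
  for (arma::uword i = 0; i < N; ++i) {
    double m = LL.row(i).max();
    arma::rowvec w = arma::exp(LL.row(i) - m);
    double s = arma::accu(w);
    post.row(i) = w / s;
    ll += m + std::log(s);
  }
  return ll;
}

// Expand per-group success probabilities to the J x L profile table
static arma::mat expand_probs(const std::vector<arma::vec>& p,
                              const arma::imat& G) {
  const arma::uword J = G.n_rows, L = G.n_cols;
  arma::mat P(J, L);
  for (arma::uword j = 0; j < J; ++j)
    for (arma::uword l = 0; l < L; ++l)
      P(j, l) = p[j](G(j, l) - 1);
  return P;
}

// [[Rcpp::export(name = ".em_fit_cpp")]]
List em_fit_cpp(const arma::mat& X, const arma::imat& G, List init_p,
                arma::vec pi, int max_iter, double tol_p, double tol_ll,
                double pmin, double pmax) {
  const arma::uword N = X.n_rows, J = X.n_cols, L = G.n_cols;
  if (G.n_rows != J) stop("group index matrix does not match the data");

  std::vector<arma::vec> p(J);
  for (arma::uword j = 0; j < J; ++j) p[j] = as<arma::vec>(init_p[j]);

  arma::mat post;
  std::vector<double> traj;
  traj.reserve(std::min(max_iter + 1, 4096));
  bool converged = false;
  int iter = 0;
  double ll_prev = -arma::datum::inf;

  for (iter = 1; iter <= max_iter; ++iter) {
    arma::mat P = expand_probs(p, G);
    double ll = e_step_ll(X, P, pi, post);      // posteriors under current params
    traj.push_back(ll);

    arma::rowvec nl = arma::sum(post, 0);       // expected class counts, 1 x L
    arma::mat Rjl = X.t() * post;               // expected correct, J x L

    double delta = 0.0;
    for (arma::uword j = 0; j < J; ++j) {
      arma::uword ng = p[j].n_elem;
      arma::vec num(ng, arma::fill::zeros), den(ng, arma::fill::zeros);
      for (arma::uword l = 0; l < L; ++l) {
        num(G(j, l) - 1) += Rjl(j, l);
        den(G(j, l) - 1) += nl(l);
      }
      for (arma::uword g = 0; g < ng; ++g) {
        if (den(g) < 1e-8) continue;            // empty latent group: keep value
        double pnew = std::min(std::max(num(g) / den(g), pmin), pmax);
        delta = std::max(delta, std::fabs(pnew - p[j](g)));
        p[j](g) = pnew;
      }
    }
    arma::vec pinew = nl.t() / (double) N;
    delta = std::max(delta, arma::abs(pinew - pi).max());
    pi = pinew;

    if (!std::isfinite(ll)) stop("non-finite marginal log-likelihood during EM");
    if (delta < tol_p || (iter > 1 && std::fabs(ll - ll_prev) < tol_ll)) {
      converged = true;
      break;
    }
    ll_prev = ll;
  }
  if (iter > max_iter) iter = max_iter;

  // final E-step so the returned posterior/log-likelihood match the
  // returned parameter values
  arma::mat P = expand_probs(p, G);
  double ll_final = e_step_ll(X, P, pi, post);
  traj.push_back(ll_final);

  List pout(J);
  for (arma::uword j = 0; j < J; ++j) pout[j] = NumericVector(p[j].begin(), p[j].end());
  return List::create(
    _["p"] = pout,
    _["pi"] = NumericVector(pi.begin(), pi.end()),
    _["posterior"] = post,
    _["loglik"] = ll_final,
    _["trajectory"] = NumericVector(traj.begin(), traj.end()),
    _["niter"] = iter,
    _["converged"] = converged);
}
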