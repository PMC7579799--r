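// Weighted maximum-likelihood fitting of the cumulative-logit
// (proportional-odds) model in the "greater-or-equal" parameterisation
//
//   logit P(Y >= k) = alpha_k + x'beta,   k = 1..K-1,  Y in {0..K-1}
//
// so alpha_k is strictly decreasing in k and beta > 0 means higher x
// pushes probability mass toward higher categories.  Newton-Raphson with
// analytic gradient and Hessian, step-halving, and a ridge fallback when
// the Hessian is near-singular.  The same routine serves as the M-step of
// the graded response model EM (single covariate = quadrature node, case
// weights = expected counts).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double plogis_(double x) {
  if (x > 0) {
    double e = std::exp(-x);
    return 1.0 / (1.0 + e);
  }
  double e = std::exp(x);
  return e / (1.0 + e);
}

// log-likelihood for parameter vector th = (alpha_1..alpha_{K-1}, beta);
// returns -Inf if any observation probability is non-positive
static double polr_loglik(const arma::ivec& y, const arma::mat& X,
                          const arma::vec& w, int K, const arma::vec& th) {
  int n = y.n_elem, p = X.n_cols;
  arma::vec alpha = th.subvec(0, K - 2);
  arma::vec beta = (p > 0) ? th.subvec(K - 1, K - 2 + p) : arma::vec();
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    if (w[i] <= 0) continue;
    double xb = 0.0;
    for (int m = 0; m < p; ++m) xb += X(i, m) * beta[m];
    int u = y[i];
    double Fu = (u >= 1) ? plogis_(alpha[u - 1] + xb) : 1.0;
    double Fv = (u + 1 <= K - 1) ? plogis_(alpha[u] + xb) : 0.0;
    double pr = Fu - Fv;
    if (!(pr > 0.0)) return -std::numeric_limits<double>::infinity();
    ll += w[i] * std::log(pr);
  }
  return ll;
}

// [[Rcpp::export(name = ".polr_newton_cpp")]]
List polr_newton_cpp(IntegerVector y_, NumericMatrix X_, NumericVector w_,
                     int K, NumericVector start_,
                     int max_iter = 100, double tol = 1e-10) {
  arma::ivec y(y_.size());
  for (int i = 0; i < y_.size(); ++i) y[i] = y_[i];
  arma::mat X(X_.begin(), X_.nrow(), X_.ncol(), false);
  arma::vec w(w_.begin(), w_.size(), false);
  int p = X.n_cols, npar = K - 1 + p;
  arma::vec th(start_.begin(), start_.size());

  double ll = polr_loglik(y, X, w, K, th);
  if (!std::isfinite(ll)) stop("invalid starting values for polr fit");

  bool converged = false;
  int iter = 0;
  arma::vec grad(npar);
  arma::mat hess(npar, npar);

  for (iter = 0; iter < max_iter; ++iter) {
    grad.zeros();
    hess.zeros();
    arma::vec alpha = th.subvec(0, K - 2);
    arma::vec beta = (p > 0) ? th.subvec(K - 1, K - 2 + p) : arma::vec();

    for (unsigned int i = 0; i < y.n_elem; ++i) {
      if (w[i] <= 0) continue;
      double xb = 0.0;
      for (int m = 0; m < p; ++m) xb += X(i, m) * beta[m];
      int u = y[i];
      bool hasU = (u >= 1), hasV = (u + 1 <= K - 1);
      double Fu = hasU ? plogis_(alpha[u - 1] + xb) : 1.0;
      double Fv = hasV ? plogis_(alpha[u] + xb) : 0.0;
      double pr = Fu - Fv;
      double gu = hasU ? Fu * (1.0 - Fu) : 0.0;
      double gv = hasV ? Fv * (1.0 - Fv) : 0.0;
      double du = gu / pr, dv = gv / pr;
      // second derivatives of log p wrt the two active linear predictors
      double A = hasU ? (gu * (1.0 - 2.0 * Fu)) / pr - du * du : 0.0;
      double B = hasV ? -(gv * (1.0 - 2.0 * Fv)) / pr - dv * dv : 0.0;
      double C = (hasU && hasV) ? du * dv : 0.0;
      double wi = w[i];

      if (hasU) grad[u - 1] += wi * du;
      if (hasV) grad[u] -= wi * dv;
      if (hasU) hess(u - 1, u - 1) += wi * A;
      if (hasV) hess(u, u) += wi * B;
      if (hasU && hasV) {
        hess(u - 1, u) += wi * C;
        hess(u, u - 1) += wi * C;
      }
      if (p > 0) {
        double gb = du - dv;                // d log p / d xb
        double hb = A + B + 2.0 * C;        // d2 log p / d xb^2
        for (int m = 0; m < p; ++m) {
          double xm = X(i, m);
          grad[K - 1 + m] += wi * gb * xm;
          if (hasU) hess(u - 1, K - 1 + m) += wi * (A + C) * xm;
          if (hasV) hess(u, K - 1 + m) += wi * (B + C) * xm;
          for (int m2 = 0; m2 <= m; ++m2)
            hess(K - 1 + m, K - 1 + m2) += wi * hb * xm * X(i, m2);
        }
      }
    }
    // symmetrise
    for (int a = 0; a < npar; ++a)
      for (int b = a + 1; b < npar; ++b) {
        if (a < K - 1 && b >= K - 1) hess(b, a) = hess(a, b);
        else if (a >= K - 1) hess(a, b) = hess(b, a);
      }

    double gmax = arma::abs(grad).max();
    if (gmax < 1e-9) { converged = true; break; }

    arma::mat nH = -hess;
    arma::vec step;
    bool ok = arma::solve(step, nH, grad, arma::solve_opts::no_approx);
    if (!ok) {
      nH.diag() += 1e-6 * (1.0 + arma::abs(nH.diag()).max());
      ok = arma::solve(step, nH, grad);
      if (!ok) break;
    }
    // step-halving to guarantee ascent and valid category probabilities
    double t = 1.0, llNew = -std::numeric_limits<double>::infinity();
    arma::vec thNew;
    for (int h = 0; h < 40; ++h) {
      thNew = th + t * step;
      llNew = polr_loglik(y, X, w, K, thNew);
      if (std::isfinite(llNew) && llNew >= ll - 1e-12) break;
      t *= 0.5;
    }
    if (!std::isfinite(llNew)) break;
    double dll = llNew - ll;
    th = thNew;
    ll = llNew;
    if (std::fabs(dll) < tol * (std::fabs(ll) + 1.0) && gmax < 1e-5) {
      converged = true;
      break;
    }
  }

  NumericVector alpha_out(K - 1), beta_out(p);
  for (int k = 0; k < K - 1; ++k) alpha_out[k] = th[k];
  for (int m = 0; m < p; ++m) beta_out[m] = th[K - 1 + m];
  return List::create(_["alpha"] = alpha_out, _["beta"] = beta_out,
                      _["loglik"] = ll, _["converged"] = converged,
                      _["iter"] = iter + 1);
}
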