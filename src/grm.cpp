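// E-step and EAP scoring kernels for the graded response model.
//
// Items may have different category counts (sparse categories can be
// collapsed upstream).  Missing responses are coded -1 and contribute
// nothing to the likelihood.  Group-specific calibration of flagged items
// is handled upstream by expanding such items into per-group pseudo-items
// that are missing for the other group, so these kernels only ever see a
// plain one-group-per-column problem.

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

// category probability table for one item: Q x K
static arma::mat item_trace(double a, const arma::vec& b,
                            const arma::vec& grid) {
  int Q = grid.n_elem, K = b.n_elem + 1;
  arma::mat P(Q, K);
  for (int q = 0; q < Q; ++q) {
    double prev = 1.0;
    for (int k = 1; k <= K; ++k) {
      double F = (k <= K - 1) ? plogis_(a * (grid[q] - b[k - 1])) : 0.0;
      P(q, k - 1) = prev - F;
      prev = F;
    }
  }
  return P;
}

// [[Rcpp::export(name = ".grm_estep_cpp")]]
List grm_estep_cpp(IntegerMatrix resp, NumericVector a, List b,
                   NumericVector grid_, NumericVector wq_,
                   bool want_scores = false) {
  int n = resp.nrow(), J = resp.ncol(), Q = grid_.size();
  arma::vec grid(grid_.begin(), Q, false);
  arma::vec wq(wq_.begin(), Q, false);

  std::vector<arma::mat> trace(J);
  for (int j = 0; j < J; ++j) {
    arma::vec bj = as<arma::vec>(b[j]);
    trace[j] = item_trace(a[j], bj, grid);
  }

  // joint likelihood of each response pattern at each node
  arma::mat L(n, Q, arma::fill::ones);
  for (int j = 0; j < J; ++j) {
    const arma::mat& T = trace[j];
    for (int i = 0; i < n; ++i) {
      int y = resp(i, j);
      if (y < 0) continue;
      for (int q = 0; q < Q; ++q) L(i, q) *= T(q, y);
    }
  }

  double loglik = 0.0;
  arma::vec theta, se;
  if (want_scores) { theta.set_size(n); se.set_size(n); }

  List r_out(J);
  std::vector<arma::mat> r(J);
  for (int j = 0; j < J; ++j) {
    arma::vec bj = as<arma::vec>(b[j]);
    r[j].zeros(Q, bj.n_elem + 1);
  }

  arma::rowvec post(Q);
  for (int i = 0; i < n; ++i) {
    double tot = 0.0;
    for (int q = 0; q < Q; ++q) {
      post[q] = L(i, q) * wq[q];
      tot += post[q];
    }
    loglik += std::log(tot);
    post /= tot;
    if (want_scores) {
      double m = 0.0, m2 = 0.0;
      for (int q = 0; q < Q; ++q) {
        m += post[q] * grid[q];
        m2 += post[q] * grid[q] * grid[q];
      }
      theta[i] = m;
      double v = m2 - m * m;
      se[i] = std::sqrt(v > 0 ? v : 0);
    }
    for (int j = 0; j < J; ++j) {
      int y = resp(i, j);
      if (y < 0) continue;
      for (int q = 0; q < Q; ++q) r[j](q, y) += post[q];
    }
  }
  for (int j = 0; j < J; ++j) r_out[j] = wrap(r[j]);

  List out = List::create(_["loglik"] = loglik, _["r"] = r_out);
  if (want_scores) {
    out["theta"] = wrap(theta);
    out["se"] = wrap(se);
  }
  return out;
}
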