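// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Negative log-likelihood of a continuous-time Markov multi-state model
// observed as snapshots. Intensities q_rs(z) = exp(logq_rs + beta_rs . z);
// transition probabilities P(dt; z) = expm(Q(z) * dt). Intervals sharing
// (dt, z) are grouped so the matrix exponential is evaluated once per
// unique configuration.
//
// par: log q for each allowed transition, then beta column-major
//      (n_trans x n_cov).
// trans_from/trans_to: 0-based state indices of the allowed transitions.
// uq_dt: unique interval lengths; uq_z: matching covariate rows
//      (n_unique x n_cov, possibly zero columns).
// group: 0-based unique-configuration index per interval.
// from/to: 0-based observed states bounding each interval.
// [[Rcpp::export]]
double cpp_ctmc_nll(const arma::vec& par, int n_states,
                    const arma::ivec& trans_from, const arma::ivec& trans_to,
                    const arma::vec& uq_dt, const arma::mat& uq_z,
                    const arma::ivec& group, const arma::ivec& from,
                    const arma::ivec& to) {
  const int ntr = trans_from.n_elem;
  const int ncov = uq_z.n_cols;
  const int nu = uq_dt.n_elem;
  arma::vec logq = par.subvec(0, ntr - 1);
  arma::mat beta(ntr, ncov);
  for (int c = 0; c < ncov; ++c)
    beta.col(c) = par.subvec(ntr + c * ntr, ntr + (c + 1) * ntr - 1);

  arma::cube P(n_states, n_states, nu);
  for (int u = 0; u < nu; ++u) {
    arma::mat Q(n_states, n_states, arma::fill::zeros);
    for (int t = 0; t < ntr; ++t) {
      double lq = logq(t);
      for (int c = 0; c < ncov; ++c) lq += beta(t, c) * uq_z(u, c);
      if (lq > 25.0) lq = 25.0;  // guard against overflow during search
      double q = std::exp(lq);
      Q(trans_from(t), trans_to(t)) += q;
      Q(trans_from(t), trans_from(t)) -= q;
    }
    P.slice(u) = arma::expmat(Q * uq_dt(u));
  }

  double nll = 0.0;
  for (arma::uword i = 0; i < from.n_elem; ++i) {
    double p = P(from(i), to(i), group(i));
    if (!(p > 1e-300)) p = 1e-300;
    nll -= std::log(p);
  }
  if (!std::isfinite(nll)) nll = 1e12;
  return nll;
}

// Matrix exponential (used for transition-probability accessors).
// [[Rcpp::export]]
arma::mat cpp_expm(const arma::mat& A) {
  return arma::expmat(A);
}

// Per-row standard deviation of subsample medians: for each row of Y,
// compute the median of Y[row, idx[, r]] for every replicate r and return
// the SD across replicates. idx is 1-based (n x reps).
// [[Rcpp::export]]
NumericVector cpp_median_sd(const NumericMatrix& Y,
                            const IntegerMatrix& idx) {
  const int G = Y.nrow(), n = idx.nrow(), reps = idx.ncol();
  NumericVector out(G);
  std::vector<double> buf(n), med(reps);
  for (int g = 0; g < G; ++g) {
    for (int r = 0; r < reps; ++r) {
      for (int i = 0; i < n; ++i) buf[i] = Y(g, idx(i, r) - 1);
      int h = n / 2;
      std::nth_element(buf.begin(), buf.begin() + h, buf.begin() + n);
      double m = buf[h];
      if (n % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + h);
        m = 0.5 * (m + lo);
      }
      med[r] = m;
    }
    double s = 0.0, ss = 0.0;
    for (int r = 0; r < reps; ++r) { s += med[r]; ss += med[r] * med[r]; }
    double mean = s / reps;
    out[g] = std::sqrt(std::max(0.0, (ss - reps * mean * mean) /
                                          (reps - 1.0)));
  }
  return out;
}
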