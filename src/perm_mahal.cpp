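// Batched permutation-subsampled Mahalanobis deviation.
//
// For one bin: outer loop over random edge subsets (size k), inner loop
// over random control subsets. Controls missing any drawn edge are
// excluded from that draw; the draw is discarded if fewer than
// min_complete complete controls remain. A patient missing any drawn
// edge skips that whole outer draw. The Ledoit-Wolf (or fixed-intensity)
// shrinkage covariance of each retained control subset is inverted once
// and its quadratic form evaluated for every eligible patient, so the
// control-side work is shared across patients.
//
// The Ledoit-Wolf dispersion term uses the identity
//   sum_i ||x_i x_i' - S||_F^2 = sum_i ||x_i||^4 - m ||S||_F^2
// (x_i centered, S = X'X/m), avoiding the per-observation outer products.

#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::mat shrunk_cov(const arma::mat& X, int method, double lambda,
                            double& intensity) {
  const arma::uword m = X.n_rows, k = X.n_cols;
  arma::rowvec mu = arma::mean(X, 0);
  arma::mat Xc = X.each_row() - mu;
  arma::mat S = (Xc.t() * Xc) / (double)m;
  double mu_t = arma::trace(S) / (double)k;
  arma::mat target = mu_t * arma::eye<arma::mat>(k, k);
  double rho;
  if (method == 1) {
    rho = lambda;
  } else {
    double d2 = arma::accu(arma::square(S - target));
    if (d2 <= std::numeric_limits<double>::epsilon()) {
      rho = 1.0;
    } else {
      arma::vec rn = arma::sum(arma::square(Xc), 1);
      double b2bar = (arma::accu(arma::square(rn)) / (double)m -
                      arma::accu(arma::square(S))) / (double)m;
      if (b2bar < 0.0) b2bar = 0.0;
      rho = std::min(b2bar, d2) / d2;
    }
  }
  intensity = rho;
  return rho * target + (1.0 - rho) * S;
}

// controls, patients: subjects x n_edges value matrices (NaN/NA = missing).
// edge_sub: n_outer x k, 1-based column indices into the value matrices.
// ctrl_sub: (n_outer * n_inner) x n_draw, 1-based control row indices,
//           row o * n_inner + i holds inner draw i of outer draw o.
// method: 0 = Ledoit-Wolf, 1 = fixed intensity lambda.
// [[Rcpp::export]]
List cpp_perm_mahal(const arma::mat& controls, const arma::mat& patients,
                    const arma::umat& edge_sub, const arma::umat& ctrl_sub,
                    int n_inner, int min_complete, int method, double lambda,
                    bool squared) {
  const arma::uword n_outer = edge_sub.n_rows;
  const arma::uword k = edge_sub.n_cols;
  const arma::uword n_pat = patients.n_rows;
  const arma::uword n_ctrl = controls.n_rows;
  const arma::uword n_draw = ctrl_sub.n_cols;
  if (ctrl_sub.n_rows != n_outer * (arma::uword)n_inner)
    stop("ctrl_sub rows must equal n_outer * n_inner");

  arma::vec sumM(n_pat, arma::fill::zeros);
  arma::uvec cnt(n_pat, arma::fill::zeros);
  arma::vec sum_outer_means(n_pat, arma::fill::zeros);
  arma::uvec n_outer_used(n_pat, arma::fill::zeros);
  arma::uvec n_outer_skipped(n_pat, arma::fill::zeros);
  arma::uword inner_discarded = 0;

  arma::mat X(n_draw, k);
  arma::mat Cinv(k, k);
  arma::rowvec d(k);

  for (arma::uword o = 0; o < n_outer; ++o) {
    arma::uvec e = edge_sub.row(o).t() - 1;
    arma::mat Ce = controls.cols(e);
    arma::mat Pe = patients.cols(e);
    std::vector<bool> ctrl_ok(n_ctrl);
    for (arma::uword c = 0; c < n_ctrl; ++c)
      ctrl_ok[c] = Ce.row(c).is_finite();
    std::vector<bool> pat_ok(n_pat);
    for (arma::uword p = 0; p < n_pat; ++p)
      pat_ok[p] = Pe.row(p).is_finite();

    arma::vec outer_sum(n_pat, arma::fill::zeros);
    arma::uword outer_cnt = 0;

    for (arma::uword i = 0; i < (arma::uword)n_inner; ++i) {
      arma::uword m = 0;
      for (arma::uword dix = 0; dix < n_draw; ++dix) {
        arma::uword c = ctrl_sub(o * n_inner + i, dix) - 1;
        if (ctrl_ok[c]) X.row(m++) = Ce.row(c);
      }
      if ((int)m < min_complete) {
        ++inner_discarded;
        continue;
      }
      arma::mat Xm = X.rows(0, m - 1);
      double intensity;
      arma::mat C = shrunk_cov(Xm, method, lambda, intensity);
      if (!arma::inv_sympd(Cinv, C)) {
        if (!arma::inv(Cinv, C))
          stop("shrunk covariance is singular");
      }
      arma::rowvec mu = arma::mean(Xm, 0);
      ++outer_cnt;
      for (arma::uword p = 0; p < n_pat; ++p) {
        if (!pat_ok[p]) continue;
        d = Pe.row(p) - mu;
        double M = arma::as_scalar(d * Cinv * d.t());
        if (!squared) M = std::sqrt(std::max(M, 0.0));
        outer_sum[p] += M;
        sumM[p] += M;
        ++cnt[p];
      }
    }
    for (arma::uword p = 0; p < n_pat; ++p) {
      if (!pat_ok[p]) {
        ++n_outer_skipped[p];
      } else if (outer_cnt > 0) {
        sum_outer_means[p] += outer_sum[p] / (double)outer_cnt;
        ++n_outer_used[p];
      }
    }
  }

  arma::vec pooled(n_pat);
  arma::vec outer_mean(n_pat);
  for (arma::uword p = 0; p < n_pat; ++p) {
    pooled[p] = cnt[p] > 0 ? sumM[p] / (double)cnt[p] : NA_REAL;
    outer_mean[p] = n_outer_used[p] > 0
      ? sum_outer_means[p] / (double)n_outer_used[p] : NA_REAL;
  }
  return List::create(
    _["M"] = pooled,
    _["M_outer"] = outer_mean,
    _["n_pairs"] = IntegerVector(cnt.begin(), cnt.end()),
    _["n_outer_used"] = IntegerVector(n_outer_used.begin(), n_outer_used.end()),
    _["n_outer_skipped"] = IntegerVector(n_outer_skipped.begin(),
                                         n_outer_skipped.end()),
    _["n_inner_discarded"] = (int)inner_discarded);
}
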