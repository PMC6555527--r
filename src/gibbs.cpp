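#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Scalar-update Gibbs sampler for a Gaussian mixed model in whitened form:
// y = X beta + sum_k Z_k alpha_k + e, alpha_kj ~ N(0, s2_k) iid,
// e ~ N(0, s2_e I). Fixed effects have a flat prior. Variances get
// scaled-inverse-chi-square updates. Missing responses are imputed each
// iteration (data augmentation), so their posterior predictive mean is the
// model's prediction for those records. Uses R's RNG, so set.seed() in R
// makes chains reproducible.
// [[Rcpp::export]]
List gibbs_core(arma::vec y, arma::uvec miss, arma::mat X, List Zlist,
                arma::vec df0, arma::vec S0, double df0e, double S0e,
                int n_iter, int burn_in, int thin) {
  const int n = y.n_elem;
  const int p = X.n_cols;
  const int K = Zlist.size();

  std::vector<arma::mat> Z(K);
  std::vector<arma::vec> zz(K);
  std::vector<arma::vec> alpha(K);
  arma::vec s2(K);
  for (int k = 0; k < K; ++k) {
    Z[k] = as<arma::mat>(Zlist[k]);
    zz[k] = arma::sum(arma::square(Z[k]), 0).t();
    alpha[k] = arma::zeros(Z[k].n_cols);
  }
  arma::vec xx = arma::sum(arma::square(X), 0).t();
  arma::vec beta = arma::zeros(p);

  // start missing responses at the observed mean
  double ymean = 0.0;
  int nobs = 0;
  for (int i = 0; i < n; ++i) {
    bool m = false;
    for (arma::uword j = 0; j < miss.n_elem; ++j) if ((int)miss[j] == i) m = true;
    if (!m) { ymean += y[i]; ++nobs; }
  }
  ymean = nobs > 0 ? ymean / nobs : 0.0;
  for (arma::uword j = 0; j < miss.n_elem; ++j) y[miss[j]] = ymean;

  double vy = arma::var(y);
  if (!(vy > 0)) vy = 1.0;
  s2.fill(vy / (2.0 * std::max(K, 1)));
  double s2e = vy / 2.0;

  arma::vec e = y - X * beta;  // alphas start at zero

  // accumulators
  arma::vec sum_s2(K, arma::fill::zeros), sumsq_s2(K, arma::fill::zeros);
  double sum_s2e = 0.0, sumsq_s2e = 0.0;
  arma::vec sum_beta(p, arma::fill::zeros);
  std::vector<arma::vec> sum_alpha(K);
  for (int k = 0; k < K; ++k) sum_alpha[k] = arma::zeros(Z[k].n_cols);
  arma::vec sum_pred(n, arma::fill::zeros);
  int n_kept = 0;

  RNGScope scope;

  for (int it = 0; it < n_iter; ++it) {
    // impute missing responses
    for (arma::uword j = 0; j < miss.n_elem; ++j) {
      int i = miss[j];
      double pred = y[i] - e[i];
      double ynew = pred + std::sqrt(s2e) * norm_rand();
      e[i] += ynew - y[i];
      y[i] = ynew;
    }
    // fixed effects (flat prior)
    for (int j = 0; j < p; ++j) {
      if (xx[j] <= 0) continue;
      double old = beta[j];
      double rhs = arma::dot(X.col(j), e) + xx[j] * old;
      double mean = rhs / xx[j];
      double bnew = mean + std::sqrt(s2e / xx[j]) * norm_rand();
      e -= X.col(j) * (bnew - old);
      beta[j] = bnew;
    }
    // random terms
    for (int k = 0; k < K; ++k) {
      const double lambda = s2e / s2[k];
      arma::vec &a = alpha[k];
      for (arma::uword j = 0; j < a.n_elem; ++j) {
        double old = a[j];
        double c = zz[k][j] + lambda;
        double rhs = arma::dot(Z[k].col(j), e) + zz[k][j] * old;
        double mean = rhs / c;
        double anew = mean + std::sqrt(s2e / c) * norm_rand();
        e -= Z[k].col(j) * (anew - old);
        a[j] = anew;
      }
      double ss = arma::dot(a, a) + df0[k] * S0[k];
      s2[k] = ss / Rf_rchisq(df0[k] + a.n_elem);
    }
    // residual variance
    double sse = arma::dot(e, e) + df0e * S0e;
    s2e = sse / Rf_rchisq(df0e + n);

    if (it >= burn_in && ((it - burn_in) % thin == 0)) {
      ++n_kept;
      for (int k = 0; k < K; ++k) {
        sum_s2[k] += s2[k];
        sumsq_s2[k] += s2[k] * s2[k];
        sum_alpha[k] += alpha[k];
      }
      sum_s2e += s2e;
      sumsq_s2e += s2e * s2e;
      sum_beta += beta;
      sum_pred += y - e;
    }
  }

  if (n_kept == 0) stop("no posterior samples kept");
  arma::vec mean_s2 = sum_s2 / n_kept;
  arma::vec sd_s2(K);
  for (int k = 0; k < K; ++k) {
    double v = sumsq_s2[k] / n_kept - mean_s2[k] * mean_s2[k];
    sd_s2[k] = std::sqrt(std::max(v, 0.0));
  }
  double mean_s2e = sum_s2e / n_kept;
  double sd_s2e = std::sqrt(std::max(sumsq_s2e / n_kept - mean_s2e * mean_s2e, 0.0));

  List alpha_means(K);
  for (int k = 0; k < K; ++k) alpha_means[k] = sum_alpha[k] / n_kept;

  return List::create(
    _["vc_mean"] = mean_s2, _["vc_sd"] = sd_s2,
    _["s2e_mean"] = mean_s2e, _["s2e_sd"] = sd_s2e,
    _["beta_mean"] = sum_beta / n_kept,
    _["alpha_mean"] = alpha_means,
    _["pred_mean"] = sum_pred / n_kept,
    _["n_kept"] = n_kept);
}
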