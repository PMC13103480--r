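#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Gibbs sampler for the kernel-regression model
//   y = mu + sum_k U_k g_k + e,   g_{ki} ~ N(0, s2_k d_{ki}),  e ~ N(0, s2_e I)
// where U_k, d_k are the (truncated) eigenvectors/values of kernel k.
// Because U_k has orthonormal columns, the full conditional of g_k is
// diagonal. Variances get scaled-inverse-chi-square updates; missing y is
// sampled by data augmentation. Uses R's RNG, so results are reproducible
// under set.seed().
// [[Rcpp::export]]
List rkhs_gibbs_cpp(NumericVector y, LogicalVector miss,
                    List Ulist, List dlist,
                    NumericVector df0, NumericVector S0,
                    double dfe, double S0e,
                    int n_burn, int n_iter, int thin) {
  const int n = y.size();
  const int K = Ulist.size();
  std::vector<arma::mat> U(K);
  std::vector<arma::vec> dv(K), g(K), u(K);
  for (int k = 0; k < K; k++) {
    U[k] = as<arma::mat>(Ulist[k]);
    dv[k] = as<arma::vec>(dlist[k]);
    g[k] = arma::zeros(dv[k].n_elem);
    u[k] = arma::zeros(n);
  }
  arma::vec yv(n);
  double obs_mean = 0.0; int nobs = 0;
  for (int i = 0; i < n; i++) if (!miss[i]) { obs_mean += y[i]; nobs++; }
  obs_mean /= nobs;
  for (int i = 0; i < n; i++) yv[i] = miss[i] ? obs_mean : y[i];

  double mu = obs_mean;
  arma::vec s2k(K);
  for (int k = 0; k < K; k++) s2k[k] = S0[k];
  double s2e = S0e;

  const int n_keep = n_iter / thin;
  double mu_sum = 0.0;
  arma::mat u_sum(n, K, arma::fill::zeros);
  arma::mat s2_draws(n_keep, K + 1, arma::fill::zeros);
  int kept = 0;

  for (int it = 0; it < n_burn + n_iter; it++) {
    arma::vec eta(n, arma::fill::zeros);
    for (int k = 0; k < K; k++) eta += u[k];
    double sd_e = std::sqrt(s2e);
    for (int i = 0; i < n; i++)
      if (miss[i]) yv[i] = mu + eta[i] + R::rnorm(0.0, sd_e);

    arma::vec e = yv - eta;
    mu = R::rnorm(arma::mean(e), std::sqrt(s2e / n));
    e -= mu;

    for (int k = 0; k < K; k++) {
      arma::vec v = e + u[k];
      arma::vec rhs = U[k].t() * v;
      const int r = dv[k].n_elem;
      double ss = 0.0;
      for (int i = 0; i < r; i++) {
        double prec = 1.0 / s2e + 1.0 / (s2k[k] * dv[k][i]);
        double mean = rhs[i] / (s2e * prec);
        g[k][i] = mean + R::rnorm(0.0, 1.0) / std::sqrt(prec);
        ss += g[k][i] * g[k][i] / dv[k][i];
      }
      u[k] = U[k] * g[k];
      e = v - u[k];
      s2k[k] = (ss + df0[k] * S0[k]) / R::rchisq(df0[k] + r);
    }
    double sse = arma::dot(e, e);
    s2e = (sse + dfe * S0e) / R::rchisq(dfe + n);

    if (it >= n_burn && (it - n_burn) % thin == thin - 1 && kept < n_keep) {
      mu_sum += mu;
      for (int k = 0; k < K; k++) {
        u_sum.col(k) += u[k];
        s2_draws(kept, k) = s2k[k];
      }
      s2_draws(kept, K) = s2e;
      kept++;
    }
  }
  return List::create(_["mu"] = mu_sum / kept,
                      _["effects"] = u_sum / kept,
                      _["s2_draws"] = s2_draws.rows(0, kept - 1),
                      _["n_kept"] = kept);
}
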