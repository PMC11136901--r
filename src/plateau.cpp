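#include <Rcpp.h>
using namespace Rcpp;

// Slot layout: for each predictor j (column j of X): c1, c2, b1, b2 at
// positions 4j .. 4j+3; the global intercept beta0 is the last slot.
// kind: 0 = free (theta_idx into theta), 1 = fixed (fixed_val),
//       2 = b2 deterministically linked: b2 = (beta0 - L) / (limit_x - c2).

static bool assemble(const NumericVector &theta,
                     const IntegerVector &kind,
                     const IntegerVector &theta_idx,
                     const NumericVector &fixed_val,
                     const NumericVector &limit_x,
                     double L, int J,
                     std::vector<double> &par) {
  int S = kind.size();
  // first pass: free and fixed (includes beta0 and all c2)
  for (int s = 0; s < S; ++s) {
    if (kind[s] == 0) par[s] = theta[theta_idx[s]];
    else if (kind[s] == 1) par[s] = fixed_val[s];
  }
  double beta0 = par[S - 1];
  // second pass: linked slopes
  for (int j = 0; j < J; ++j) {
    for (int o = 2; o < 4; ++o) { // b1 or b2 can be linked
      int s = 4 * j + o;
      if (kind[s] == 2) {
        double edge = (o == 3) ? par[4 * j + 1] : par[4 * j]; // c2 or c1
        double gap = (o == 3) ? (limit_x[s] - edge) : (edge - limit_x[s]);
        if (gap <= 0.0 || beta0 <= L) return false;
        par[s] = (beta0 - L) / gap;
      }
    }
  }
  // validity: c1 <= c2, slopes >= 0
  for (int j = 0; j < J; ++j) {
    if (par[4 * j] > par[4 * j + 1]) return false;
    if (par[4 * j + 2] < 0.0 || par[4 * j + 3] < 0.0) return false;
  }
  return true;
}

static double log_prior(const NumericVector &theta,
                        const IntegerVector &ptype,
                        const NumericVector &p1, const NumericVector &p2,
                        const NumericVector &lower, const NumericVector &upper) {
  double lp = 0.0;
  for (int k = 0; k < theta.size(); ++k) {
    double x = theta[k];
    if (x < lower[k] || x > upper[k]) return R_NegInf;
    switch (ptype[k]) {
    case 0: break;                                   // uniform on [lower, upper]
    case 1: lp += -0.5 * (x / p1[k]) * (x / p1[k]); break;   // half-normal(sd p1)
    case 2: lp += -0.5 * ((x - p1[k]) / p2[k]) * ((x - p1[k]) / p2[k]); break;
    }
  }
  return lp;
}

static double log_lik(const NumericMatrix &X, const IntegerVector &y,
                      const std::vector<double> &par) {
  int n = X.nrow(), J = X.ncol();
  double beta0 = par[4 * J];
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double eta = beta0;
    for (int j = 0; j < J; ++j) {
      double x = X(i, j);
      double c1 = par[4 * j], c2 = par[4 * j + 1];
      double b1 = par[4 * j + 2], b2 = par[4 * j + 3];
      if (x < c1) eta -= b1 * (c1 - x);
      else if (x > c2) eta -= b2 * (x - c2);
    }
    double p = 1.0 / (1.0 + std::exp(-eta));
    if (p < 1e-12) p = 1e-12;
    if (p > 1.0 - 1e-12) p = 1.0 - 1e-12;
    ll += y[i] ? std::log(p) : std::log1p(-p);
  }
  return ll;
}

// [[Rcpp::export]]
double plateau_loglik_cpp(NumericMatrix X, IntegerVector y, NumericVector par) {
  std::vector<double> p(par.begin(), par.end());
  return log_lik(X, y, p);
}

// [[Rcpp::export]]
List plateau_mcmc_cpp(NumericMatrix X, IntegerVector y,
                      IntegerVector kind, IntegerVector theta_idx,
                      NumericVector fixed_val, NumericVector limit_x,
                      IntegerVector ptype, NumericVector p1, NumericVector p2,
                      NumericVector lower, NumericVector upper,
                      NumericVector init, double L,
                      int n_chains, int n_iter, int n_warmup,
                      int adapt_batch, double target_accept,
                      double init_jitter) {
  int K = init.size();
  int J = X.ncol();
  int S = kind.size();
  int n_keep = n_iter - n_warmup;
  std::vector<double> par(S);

  List chains(n_chains);
  NumericMatrix accept_rate(n_chains, K);
  RNGScope scope;

  for (int c = 0; c < n_chains; ++c) {
    NumericVector theta = clone(init);
    if (init_jitter > 0.0)
      for (int k = 0; k < K; ++k) theta[k] += init_jitter * norm_rand();
    double lp = log_prior(theta, ptype, p1, p2, lower, upper);
    if (R_finite(lp)) {
      if (!assemble(theta, kind, theta_idx, fixed_val, limit_x, L, J, par))
        lp = R_NegInf;
      else lp += log_lik(X, y, par);
    }
    if (!R_finite(lp))
      stop("non-finite log posterior at initialization");

    std::vector<double> lstep(K, std::log(0.1));
    std::vector<int> acc_batch(K, 0), acc_total(K, 0);
    NumericMatrix draws(n_keep, K);
    int batch_num = 0;

    for (int it = 1; it <= n_iter; ++it) {
      for (int k = 0; k < K; ++k) {
        double old = theta[k];
        theta[k] = old + std::exp(lstep[k]) * norm_rand();
        double lp_new = log_prior(theta, ptype, p1, p2, lower, upper);
        if (R_finite(lp_new)) {
          if (!assemble(theta, kind, theta_idx, fixed_val, limit_x, L, J, par))
            lp_new = R_NegInf;
          else lp_new += log_lik(X, y, par);
        }
        if (R_finite(lp_new) && std::log(unif_rand()) < lp_new - lp) {
          lp = lp_new;
          ++acc_batch[k]; ++acc_total[k];
        } else {
          theta[k] = old;
        }
      }
      if (it <= n_warmup && it % adapt_batch == 0) {
        ++batch_num;
        double gain = 1.0 / std::sqrt((double)batch_num);
        for (int k = 0; k < K; ++k) {
          double ar = (double)acc_batch[k] / adapt_batch;
          lstep[k] += gain * (ar - target_accept);
          acc_batch[k] = 0;
        }
      }
      if (it > n_warmup)
        for (int k = 0; k < K; ++k) draws(it - n_warmup - 1, k) = theta[k];
    }
    chains[c] = draws;
    for (int k = 0; k < K; ++k)
      accept_rate(c, k) = (double)acc_total[k] / n_iter;
  }
  return List::create(_["chains"] = chains, _["accept_rate"] = accept_rate);
}

// Posterior predictions: probability for every draw (rows of `par_draws`,
// assembled slot layout) at every cell (rows of X). Returns draws x cells.
// [[Rcpp::export]]
NumericMatrix plateau_predict_cpp(NumericMatrix par_draws, NumericMatrix X) {
  int D = par_draws.nrow(), n = X.nrow(), J = X.ncol();
  if (par_draws.ncol() != 4 * J + 1)
    stop("parameter draws do not match the number of predictors");
  NumericMatrix out(D, n);
  for (int d = 0; d < D; ++d) {
    double beta0 = par_draws(d, 4 * J);
    for (int i = 0; i < n; ++i) {
      double eta = beta0;
      for (int j = 0; j < J; ++j) {
        double x = X(i, j);
        double c1 = par_draws(d, 4 * j), c2 = par_draws(d, 4 * j + 1);
        if (x < c1) eta -= par_draws(d, 4 * j + 2) * (c1 - x);
        else if (x > c2) eta -= par_draws(d, 4 * j + 3) * (x - c2);
      }
      out(d, i) = 1.0 / (1.0 + std::exp(-eta));
    }
  }
  return out;
}
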