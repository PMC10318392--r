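#include <Rcpp.h>
using namespace Rcpp;

// Beta-binomial log pmf at (x, n) with shapes a = mu*kappa, b = (1-mu)*kappa.
// n == 0 carries no information: pmf of the empty observation is 1.
static inline double bb_lp(int x, int n, double lchoose_xn,
                           double a, double b, double lbeta_ab) {
  if (n == 0) return 0.0;
  return lchoose_xn + R::lbeta(x + a, n - x + b) - lbeta_ab;
}

// [[Rcpp::export(name = ".bb_logpmf_cpp")]]
NumericVector bb_logpmf_cpp(IntegerVector x, IntegerVector n,
                            NumericVector mu, NumericVector kappa) {
  R_xlen_t L = x.size();
  NumericVector out(L);
  for (R_xlen_t i = 0; i < L; ++i) {
    double a = mu[i % mu.size()] * kappa[i % kappa.size()];
    double b = (1.0 - mu[i % mu.size()]) * kappa[i % kappa.size()];
    out[i] = bb_lp(x[i], n[i], R::lchoose(n[i], x[i]), a, b, R::lbeta(a, b));
  }
  return out;
}

// Mixture log-likelihood from a cached U x 3 matrix of component log pmfs,
// log mixing weights, and per-row multiplicities w (deduplicated sites).
// [[Rcpp::export(name = ".mix_loglik_cpp")]]
double mix_loglik_cpp(NumericMatrix logcomp, NumericVector ltheta,
                      NumericVector w) {
  R_xlen_t U = logcomp.nrow();
  double ll = 0.0;
  for (R_xlen_t i = 0; i < U; ++i) {
    double t0 = ltheta[0] + logcomp(i, 0);
    double t1 = ltheta[1] + logcomp(i, 1);
    double t2 = ltheta[2] + logcomp(i, 2);
    double m = std::max(t0, std::max(t1, t2));
    ll += w[i] * (m + std::log(std::exp(t0 - m) + std::exp(t1 - m) +
                               std::exp(t2 - m)));
  }
  return ll;
}

// log( (1/S) * sum_s BB(x | n, mu_gs, kappa_gs) ) for each row and each of
// the three genotype components, averaging the component likelihood over
// posterior draws. Returns a U x 3 matrix.
// [[Rcpp::export(name = ".post_logmeanlik_cpp")]]
NumericMatrix post_logmeanlik_cpp(IntegerVector x, IntegerVector n,
                                  NumericMatrix mu_draws,
                                  NumericMatrix kappa_draws) {
  R_xlen_t U = x.size();
  int S = mu_draws.nrow();
  NumericMatrix out(U, 3);
  // precompute per-draw shapes and lbeta normalizers
  std::vector<double> a(S * 3), b(S * 3), lb(S * 3);
  for (int s = 0; s < S; ++s) {
    for (int g = 0; g < 3; ++g) {
      double as = mu_draws(s, g) * kappa_draws(s, g);
      double bs = (1.0 - mu_draws(s, g)) * kappa_draws(s, g);
      a[s * 3 + g] = as;
      b[s * 3 + g] = bs;
      lb[s * 3 + g] = R::lbeta(as, bs);
    }
  }
  std::vector<double> tmp(S);
  for (R_xlen_t i = 0; i < U; ++i) {
    double lch = R::lchoose(n[i], x[i]);
    for (int g = 0; g < 3; ++g) {
      double m = R_NegInf;
      for (int s = 0; s < S; ++s) {
        double lp = bb_lp(x[i], n[i], lch, a[s * 3 + g], b[s * 3 + g],
                          lb[s * 3 + g]);
        tmp[s] = lp;
        if (lp > m) m = lp;
      }
      double acc = 0.0;
      for (int s = 0; s < S; ++s) acc += std::exp(tmp[s] - m);
      out(i, g) = m + std::log(acc) - std::log((double)S);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Adaptive Metropolis-within-Gibbs sampler on transformed coordinates:
//   z[0], z[1]  stick-breaking logits of theta
//   z[2..4]     logit(mu_g)
//   z[5..7]     log(kappa_g)
// Target: mixture likelihood x Dirichlet(theta) x Beta(mu_g) x Gamma(kappa_g)
// with the ascending-mu identifiability constraint (proposals violating the
// ordering are rejected, i.e. the prior is truncated to the ordered region).
// Uses R's RNG so runs are reproducible under set.seed().
// ---------------------------------------------------------------------------

struct BBState {
  double z[8];
  double theta[3], mu[3], kappa[3];
  double ll;               // mixture log-likelihood
  double lp_theta;         // Dirichlet log density + stick Jacobian
  double lp_mu[3];         // Beta log density + logit Jacobian
  double lp_kappa[3];      // Gamma log density + log Jacobian
};

static inline double plogis_(double z) { return 1.0 / (1.0 + std::exp(-z)); }

static void sticks_to_theta(double t1, double t2, double* theta) {
  double v1 = plogis_(t1), v2 = plogis_(t2);
  theta[0] = v1;
  theta[1] = (1.0 - v1) * v2;
  theta[2] = (1.0 - v1) * (1.0 - v2);
}

// Dirichlet(conc) density on theta plus the log Jacobian of the
// stick-breaking transform (normalizing constant dropped).
static double lp_theta_fun(double t1, double t2, const double* theta,
                           NumericVector conc) {
  double v1 = plogis_(t1), v2 = plogis_(t2);
  double lj = std::log(v1) + 2.0 * std::log(1.0 - v1) + std::log(v2) +
              std::log(1.0 - v2);
  double ld = 0.0;
  for (int g = 0; g < 3; ++g) ld += (conc[g] - 1.0) * std::log(theta[g]);
  return ld + lj;
}

// Beta(a,b) density of mu plus logit Jacobian: a*log(mu) + b*log(1-mu) + C
static inline double lp_mu_fun(double mu, double a, double b) {
  return a * std::log(mu) + b * std::log(1.0 - mu);
}

// Gamma(shape, rate 1) density of kappa plus log Jacobian:
// shape*log(kappa) - kappa + C
static inline double lp_kappa_fun(double kappa, double shape) {
  return shape * std::log(kappa) - kappa;
}

static void recompute_col(NumericMatrix logcomp, int g, IntegerVector x,
                          IntegerVector n, NumericVector lch, double mu,
                          double kappa) {
  double a = mu * kappa, b = (1.0 - mu) * kappa;
  double lb = R::lbeta(a, b);
  R_xlen_t U = x.size();
  for (R_xlen_t i = 0; i < U; ++i)
    logcomp(i, g) = bb_lp(x[i], n[i], lch[i], a, b, lb);
}

static double mixll(NumericMatrix logcomp, const double* theta,
                    NumericVector w) {
  NumericVector lt(3);
  for (int g = 0; g < 3; ++g) lt[g] = std::log(theta[g]);
  return mix_loglik_cpp(logcomp, lt, w);
}

// [[Rcpp::export(name = ".bb_mcmc_cpp")]]
List bb_mcmc_cpp(IntegerVector x, IntegerVector n, NumericVector w,
                    NumericVector dir_conc, NumericVector alpha_hyper,
                    NumericVector beta_hyper, int n_warmup, int n_keep,
                    NumericVector z_init, NumericVector step_init) {
  R_xlen_t U = x.size();
  NumericVector lch(U);
  for (R_xlen_t i = 0; i < U; ++i) lch[i] = R::lchoose(n[i], x[i]);

  BBState st;
  for (int j = 0; j < 8; ++j) st.z[j] = z_init[j];
  sticks_to_theta(st.z[0], st.z[1], st.theta);
  for (int g = 0; g < 3; ++g) {
    st.mu[g] = plogis_(st.z[2 + g]);
    st.kappa[g] = std::exp(st.z[5 + g]);
    st.lp_mu[g] = lp_mu_fun(st.mu[g], alpha_hyper[g], beta_hyper[g]);
    st.lp_kappa[g] = lp_kappa_fun(st.kappa[g],
                                  alpha_hyper[g] + beta_hyper[g]);
  }
  st.lp_theta = lp_theta_fun(st.z[0], st.z[1], st.theta, dir_conc);

  NumericMatrix logcomp(U, 3);
  for (int g = 0; g < 3; ++g)
    recompute_col(logcomp, g, x, n, lch, st.mu[g], st.kappa[g]);
  st.ll = mixll(logcomp, st.theta, w);
  if (!R_finite(st.ll)) stop("non-finite log-likelihood at initial state");

  NumericVector lstep = clone(step_init);
  for (int j = 0; j < 8; ++j) lstep[j] = std::log(step_init[j]);
  NumericVector acc_count(8);
  int n_iter = n_warmup + n_keep;
  NumericMatrix draws(n_keep, 9);
  NumericVector ll_out(n_keep);
  NumericVector newcol(U);
  const double target_acc = 0.44;

  for (int it = 0; it < n_iter; ++it) {
    for (int j = 0; j < 8; ++j) {
      double step = std::exp(lstep[j]);
      double zprop = st.z[j] + step * R::norm_rand();
      double alpha = 0.0;  // acceptance probability
      bool accept = false;

      if (j < 2) {  // theta sticks
        double t1 = (j == 0) ? zprop : st.z[0];
        double t2 = (j == 1) ? zprop : st.z[1];
        double thp[3];
        sticks_to_theta(t1, t2, thp);
        double lp_th = lp_theta_fun(t1, t2, thp, dir_conc);
        double llp = mixll(logcomp, thp, w);
        double lr = (llp + lp_th) - (st.ll + st.lp_theta);
        alpha = std::min(1.0, std::exp(lr));
        if (R_finite(llp) && std::log(R::unif_rand()) < lr) {
          accept = true;
          st.z[j] = zprop;
          for (int g = 0; g < 3; ++g) st.theta[g] = thp[g];
          st.lp_theta = lp_th;
          st.ll = llp;
        }
      } else if (j < 5) {  // mu_g
        int g = j - 2;
        double mup = plogis_(zprop);
        // ascending-mu constraint (ordered-region truncation)
        bool ok = true;
        if (g > 0 && mup <= st.mu[g - 1]) ok = false;
        if (g < 2 && mup >= st.mu[g + 1]) ok = false;
        if (ok && mup > 0.0 && mup < 1.0) {
          double lp_m = lp_mu_fun(mup, alpha_hyper[g], beta_hyper[g]);
          for (R_xlen_t i = 0; i < U; ++i) newcol[i] = logcomp(i, g);
          recompute_col(logcomp, g, x, n, lch, mup, st.kappa[g]);
          double llp = mixll(logcomp, st.theta, w);
          double lr = (llp + lp_m) - (st.ll + st.lp_mu[g]);
          alpha = std::min(1.0, std::exp(lr));
          if (R_finite(llp) && std::log(R::unif_rand()) < lr) {
            accept = true;
            st.z[j] = zprop;
            st.mu[g] = mup;
            st.lp_mu[g] = lp_m;
            st.ll = llp;
          } else {
            for (R_xlen_t i = 0; i < U; ++i) logcomp(i, g) = newcol[i];
          }
        }
      } else {  // kappa_g
        int g = j - 5;
        double kp = std::exp(zprop);
        if (R_finite(kp) && kp > 0.0) {
          double lp_k = lp_kappa_fun(kp, alpha_hyper[g] + beta_hyper[g]);
          for (R_xlen_t i = 0; i < U; ++i) newcol[i] = logcomp(i, g);
          recompute_col(logcomp, g, x, n, lch, st.mu[g], kp);
          double llp = mixll(logcomp, st.theta, w);
          double lr = (llp + lp_k) - (st.ll + st.lp_kappa[g]);
          alpha = std::min(1.0, std::exp(lr));
          if (R_finite(llp) && std::log(R::unif_rand()) < lr) {
            accept = true;
            st.z[j] = zprop;
            st.kappa[g] = kp;
            st.lp_kappa[g] = lp_k;
            st.ll = llp;
          } else {
            for (R_xlen_t i = 0; i < U; ++i) logcomp(i, g) = newcol[i];
          }
        }
      }

      if (it < n_warmup) {
        // Robbins-Monro adaptation toward the scalar-RW optimum; frozen
        // after warmup so kept draws come from a fixed kernel.
        double gam = std::pow((double)(it + 1), -0.6);
        lstep[j] += gam * (alpha - target_acc);
      } else if (accept) {
        acc_count[j] += 1.0;
      }
    }
    if (it >= n_warmup) {
      int k = it - n_warmup;
      for (int g = 0; g < 3; ++g) {
        draws(k, g) = st.theta[g];
        draws(k, 3 + g) = st.mu[g];
        draws(k, 6 + g) = st.kappa[g];
      }
      ll_out[k] = st.ll;
    }
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector steps(8), acc(8);
  for (int j = 0; j < 8; ++j) {
    steps[j] = std::exp(lstep[j]);
    acc[j] = acc_count[j] / (double)n_keep;
  }
  return List::create(_["draws"] = draws, _["loglik"] = ll_out,
                      _["accept"] = acc, _["steps"] = steps);
}
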