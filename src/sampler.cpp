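#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for the hierarchical negative-binomial
// shark-density model: tow counts Y_t ~ NB(mean mu_i * area_t, size k),
// island densities mu_i ~ Normal(loc_i, sigma2/n_i) truncated to (0, Inf),
// loc_i = E_i (identity link) or exp(E_i) (log link),
// E_i = alpha + sum_j w_j beta_j x_ij. Random-walk step sizes adapt toward
// a 0.44 acceptance rate during burn-in only, in batches of 50, so the
// post-burn-in kernel is a fixed Markov kernel with the right invariant
// distribution.

static inline double nb_lpmf(double y, double lam, double k,
                             double lg_yk, double lg_k, double lg_y1) {
  // lg_yk = lgamma(y + k), lg_k = lgamma(k), lg_y1 = lgamma(y + 1)
  if (lam <= 0.0) return (y == 0.0) ? 0.0 : R_NegInf;
  double lkl = std::log(k + lam);
  return lg_yk - lg_k - lg_y1 + k * (std::log(k) - lkl) +
         y * (std::log(lam) - lkl);
}

static inline double tn_lpdf(double mu, double loc, double sd) {
  if (mu <= 0.0) return R_NegInf;
  return R::dnorm(mu, loc, sd, 1) - R::pnorm(loc / sd, 0.0, 1.0, 1, 1);
}

struct Cache {
  std::vector<double> lg_yk;  // lgamma(uy + k) per unique count
  double lg_k;
};

// [[Rcpp::export(name = ".mcmc_chain_cpp")]]
List mcmc_chain_cpp(IntegerVector y, NumericVector area, IntegerVector island,
                    NumericMatrix X, IntegerVector n_i,
                    IntegerVector isl_start, IntegerVector isl_len,
                    int n_iter, int n_burn,
                    List priors, bool log_link, bool selection,
                    bool weight_by_n,
                    double alpha0, NumericVector beta0, IntegerVector w0,
                    NumericVector mu0, double sigma20, double k0,
                    bool fix_sigma2, bool fix_k, bool fix_w) {
  const int T = y.size();
  const int nI = n_i.size();
  const int p = X.ncol();

  const double coef_mean = priors["coef_mean"];
  const double coef_var  = priors["coef_var"];
  const double coef_sd   = std::sqrt(coef_var);
  const double hv_a = priors["hypervar_gamma_shape"];
  const double hv_b = priors["hypervar_gamma_rate"];
  const double k_a  = priors["k_gamma_shape"];
  const double k_b  = priors["k_gamma_rate"];
  const double w_p  = priors["indicator_prob"];
  const double lw1 = std::log(w_p), lw0 = std::log1p(-w_p);

  // unique count values -> lgamma caches
  std::vector<double> uy;
  std::vector<int> uidx(T);
  {
    std::map<int, int> seen;
    for (int t = 0; t < T; ++t) {
      auto it = seen.find(y[t]);
      if (it == seen.end()) {
        seen[y[t]] = (int)uy.size();
        uidx[t] = (int)uy.size();
        uy.push_back((double)y[t]);
      } else uidx[t] = it->second;
    }
  }
  const int U = (int)uy.size();
  std::vector<double> lg_y1(U);
  for (int u = 0; u < U; ++u) lg_y1[u] = R::lgammafn(uy[u] + 1.0);

  Cache ck;
  ck.lg_yk.resize(U);
  auto set_k_cache = [&](Cache &c, double k) {
    c.lg_k = R::lgammafn(k);
    for (int u = 0; u < U; ++u) c.lg_yk[u] = R::lgammafn(uy[u] + k);
  };

  // state
  double alpha = alpha0, sigma2 = sigma20, kpar = k0;
  std::vector<double> beta(beta0.begin(), beta0.end());
  std::vector<int> w(w0.begin(), w0.end());
  std::vector<double> mu(mu0.begin(), mu0.end());
  set_k_cache(ck, kpar);

  std::vector<double> E(nI), loc(nI), sd_i(nI);
  auto recompute_E = [&]() {
    for (int i = 0; i < nI; ++i) {
      double e = alpha;
      for (int j = 0; j < p; ++j) if (w[j]) e += beta[j] * X(i, j);
      E[i] = e;
      loc[i] = log_link ? std::exp(e) : e;
    }
  };
  auto recompute_sd = [&]() {
    for (int i = 0; i < nI; ++i)
      sd_i[i] = std::sqrt(weight_by_n ? sigma2 / n_i[i] : sigma2);
  };
  recompute_E();
  recompute_sd();

  // island NB log likelihood at current k cache
  auto isl_ll = [&](int i, double mui, const Cache &c, double k) {
    double s = 0.0;
    int st = isl_start[i], L = isl_len[i];
    for (int t = st; t < st + L; ++t) {
      double lam = mui * area[t];
      s += nb_lpmf((double)y[t], lam, k, c.lg_yk[uidx[t]], c.lg_k,
                   lg_y1[uidx[t]]);
    }
    return s;
  };

  std::vector<double> llmu(nI);   // per-island NB loglik
  std::vector<double> lpmu(nI);   // per-island truncnorm log density
  for (int i = 0; i < nI; ++i) {
    llmu[i] = isl_ll(i, mu[i], ck, kpar);
    lpmu[i] = tn_lpdf(mu[i], loc[i], sd_i[i]);
  }

  // adaptive step sizes (log scale)
  double ls_alpha = std::log(0.1);
  std::vector<double> ls_beta(p, std::log(0.1));
  std::vector<double> ls_mu(nI, std::log(0.2));
  double ls_s2 = std::log(0.5), ls_k = std::log(0.3);
  int acc_alpha = 0, try_alpha = 0;
  std::vector<int> acc_beta(p, 0), try_beta(p, 0);
  std::vector<int> acc_mu(nI, 0), try_mu(nI, 0);
  int acc_s2 = 0, try_s2 = 0, acc_k = 0, try_k = 0;
  long tot_acc_mu = 0, tot_try_mu = 0;
  long tot_acc_beta = 0, tot_try_beta = 0;
  long tot_acc_alpha = 0, tot_try_alpha = 0;
  long tot_acc_s2 = 0, tot_try_s2 = 0, tot_acc_k = 0, tot_try_k = 0;
  int batch = 0;

  const int keep = n_iter - n_burn;
  const int npar = 1 + 2 * p + nI + 2;
  NumericMatrix out(keep, npar);

  RNGScope scope;
  Cache ck_prop;
  ck_prop.lg_yk.resize(U);

  auto adapt = [&](double &ls, int acc, int tries, int batch_no) {
    if (tries == 0) return;
    double delta = std::min(0.05, 1.0 / std::sqrt((double)batch_no));
    if ((double)acc / tries > 0.44) ls += delta; else ls -= delta;
    if (ls < -8.0) ls = -8.0;
    if (ls > 4.0) ls = 4.0;
  };

  for (int it = 0; it < n_iter; ++it) {
    // ---- alpha ----
    {
      double prop = alpha + R::norm_rand() * std::exp(ls_alpha);
      double dlp = R::dnorm(prop, coef_mean, coef_sd, 1) -
                   R::dnorm(alpha, coef_mean, coef_sd, 1);
      std::vector<double> lpmu_new(nI);
      for (int i = 0; i < nI; ++i) {
        double e = E[i] + (prop - alpha);
        double l = log_link ? std::exp(e) : e;
        lpmu_new[i] = tn_lpdf(mu[i], l, sd_i[i]);
        dlp += lpmu_new[i] - lpmu[i];
      }
      ++try_alpha; ++tot_try_alpha;
      if (std::log(R::unif_rand()) < dlp) {
        double d = prop - alpha;
        alpha = prop;
        for (int i = 0; i < nI; ++i) {
          E[i] += d;
          loc[i] = log_link ? std::exp(E[i]) : E[i];
          lpmu[i] = lpmu_new[i];
        }
        ++acc_alpha; ++tot_acc_alpha;
      }
    }
    // ---- beta_j ----
    for (int j = 0; j < p; ++j) {
      if (selection && w[j] == 0) {
        // coefficient drops out of the likelihood: full conditional = prior
        beta[j] = coef_mean + coef_sd * R::norm_rand();
        continue;
      }
      double prop = beta[j] + R::norm_rand() * std::exp(ls_beta[j]);
      double dlp = R::dnorm(prop, coef_mean, coef_sd, 1) -
                   R::dnorm(beta[j], coef_mean, coef_sd, 1);
      std::vector<double> lpmu_new(nI);
      double db = prop - beta[j];
      for (int i = 0; i < nI; ++i) {
        double e = E[i] + db * X(i, j);
        double l = log_link ? std::exp(e) : e;
        lpmu_new[i] = tn_lpdf(mu[i], l, sd_i[i]);
        dlp += lpmu_new[i] - lpmu[i];
      }
      ++try_beta[j]; ++tot_try_beta;
      if (std::log(R::unif_rand()) < dlp) {
        for (int i = 0; i < nI; ++i) {
          E[i] += db * X(i, j);
          loc[i] = log_link ? std::exp(E[i]) : E[i];
          lpmu[i] = lpmu_new[i];
        }
        beta[j] = prop;
        ++acc_beta[j]; ++tot_acc_beta;
      }
    }
    // ---- w_j flips ----
    if (selection && !fix_w) {
      for (int j = 0; j < p; ++j) {
        int wn = 1 - w[j];
        double sgn = (wn == 1) ? 1.0 : -1.0;
        double dlp = (wn == 1) ? (lw1 - lw0) : (lw0 - lw1);
        std::vector<double> lpmu_new(nI);
        for (int i = 0; i < nI; ++i) {
          double e = E[i] + sgn * beta[j] * X(i, j);
          double l = log_link ? std::exp(e) : e;
          lpmu_new[i] = tn_lpdf(mu[i], l, sd_i[i]);
          dlp += lpmu_new[i] - lpmu[i];
        }
        if (std::log(R::unif_rand()) < dlp) {
          for (int i = 0; i < nI; ++i) {
            E[i] += sgn * beta[j] * X(i, j);
            loc[i] = log_link ? std::exp(E[i]) : E[i];
            lpmu[i] = lpmu_new[i];
          }
          w[j] = wn;
        }
      }
    }
    // ---- mu_i ----
    for (int i = 0; i < nI; ++i) {
      double prop = mu[i] + R::norm_rand() * std::exp(ls_mu[i]);
      ++try_mu[i]; ++tot_try_mu;
      if (prop <= 0.0) continue;
      double ll_new = isl_ll(i, prop, ck, kpar);
      double lp_new = tn_lpdf(prop, loc[i], sd_i[i]);
      double dlp = (ll_new - llmu[i]) + (lp_new - lpmu[i]);
      if (std::log(R::unif_rand()) < dlp) {
        mu[i] = prop; llmu[i] = ll_new; lpmu[i] = lp_new;
        ++acc_mu[i]; ++tot_acc_mu;
      }
    }
    // ---- sigma2 (log-scale RW) ----
    if (!fix_sigma2) {
      double prop = sigma2 * std::exp(R::norm_rand() * std::exp(ls_s2));
      // inverse-gamma(hv_a, hv_b) on sigma2 + Jacobian of the log move
      double dlp = -(hv_a + 1.0) * (std::log(prop) - std::log(sigma2)) -
                   hv_b * (1.0 / prop - 1.0 / sigma2) +
                   (std::log(prop) - std::log(sigma2));
      std::vector<double> lpmu_new(nI);
      for (int i = 0; i < nI; ++i) {
        double s = std::sqrt(weight_by_n ? prop / n_i[i] : prop);
        lpmu_new[i] = tn_lpdf(mu[i], loc[i], s);
        dlp += lpmu_new[i] - lpmu[i];
      }
      ++try_s2; ++tot_try_s2;
      if (std::log(R::unif_rand()) < dlp) {
        sigma2 = prop;
        recompute_sd();
        for (int i = 0; i < nI; ++i) lpmu[i] = lpmu_new[i];
        ++acc_s2; ++tot_acc_s2;
      }
    }
    // ---- k (log-scale RW) ----
    if (!fix_k) {
      double prop = kpar * std::exp(R::norm_rand() * std::exp(ls_k));
      set_k_cache(ck_prop, prop);
      double ll_new_tot = 0.0;
      std::vector<double> ll_new(nI);
      for (int i = 0; i < nI; ++i) {
        ll_new[i] = isl_ll(i, mu[i], ck_prop, prop);
        ll_new_tot += ll_new[i] - llmu[i];
      }
      double dlp = ll_new_tot +
                   (k_a - 1.0) * (std::log(prop) - std::log(kpar)) -
                   k_b * (prop - kpar) +
                   (std::log(prop) - std::log(kpar));
      ++try_k; ++tot_try_k;
      if (std::log(R::unif_rand()) < dlp) {
        kpar = prop;
        std::swap(ck.lg_yk, ck_prop.lg_yk);
        ck.lg_k = ck_prop.lg_k;
        for (int i = 0; i < nI; ++i) llmu[i] = ll_new[i];
        ++acc_k; ++tot_acc_k;
      }
    }
    // ---- adapt during burn-in ----
    if (it < n_burn && ((it + 1) % 50 == 0)) {
      ++batch;
      adapt(ls_alpha, acc_alpha, try_alpha, batch);
      acc_alpha = try_alpha = 0;
      for (int j = 0; j < p; ++j) {
        adapt(ls_beta[j], acc_beta[j], try_beta[j], batch);
        acc_beta[j] = try_beta[j] = 0;
      }
      for (int i = 0; i < nI; ++i) {
        adapt(ls_mu[i], acc_mu[i], try_mu[i], batch);
        acc_mu[i] = try_mu[i] = 0;
      }
      adapt(ls_s2, acc_s2, try_s2, batch); acc_s2 = try_s2 = 0;
      adapt(ls_k, acc_k, try_k, batch); acc_k = try_k = 0;
    }
    // ---- store ----
    if (it >= n_burn) {
      int r = it - n_burn, c = 0;
      out(r, c++) = alpha;
      for (int j = 0; j < p; ++j) out(r, c++) = beta[j];
      for (int j = 0; j < p; ++j) out(r, c++) = (double)w[j];
      for (int i = 0; i < nI; ++i) out(r, c++) = mu[i];
      out(r, c++) = sigma2;
      out(r, c++) = kpar;
    }
  }

  NumericVector acc = NumericVector::create(
    _["alpha"] = tot_try_alpha ? (double)tot_acc_alpha / tot_try_alpha : NA_REAL,
    _["beta"]  = tot_try_beta ? (double)tot_acc_beta / tot_try_beta : NA_REAL,
    _["mu"]    = tot_try_mu ? (double)tot_acc_mu / tot_try_mu : NA_REAL,
    _["sigma2"] = tot_try_s2 ? (double)tot_acc_s2 / tot_try_s2 : NA_REAL,
    _["k"]     = tot_try_k ? (double)tot_acc_k / tot_try_k : NA_REAL);
  return List::create(_["draws"] = out, _["acceptance"] = acc);
}

// Posterior-predictive discrepancy: at each retained draw, simulate one
// replicate count per tow from NB(mu_i * area_t, k) and return the sum of
// squared residuals for the observed and the replicate data.
// [[Rcpp::export(name = ".pp_discrepancy_cpp")]]
List pp_discrepancy_cpp(NumericMatrix mu_draws, NumericVector k_draws,
                        IntegerVector island, NumericVector area,
                        IntegerVector y) {
  const int S = mu_draws.nrow();
  const int T = y.size();
  NumericVector d_obs(S), d_rep(S);
  RNGScope scope;
  for (int s = 0; s < S; ++s) {
    double k = k_draws[s];
    double dobs = 0.0, drep = 0.0;
    for (int t = 0; t < T; ++t) {
      double lam = mu_draws(s, island[t] - 1) * area[t];
      double e1 = (double)y[t] - lam;
      dobs += e1 * e1;
      // NB(mu = lam, size = k) as the gamma-Poisson mixture
      double yr = 0.0;
      if (lam > 0.0) {
        double g = R::rgamma(k, lam / k);
        yr = R::rpois(g);
      }
      double e2 = yr - lam;
      drep += e2 * e2;
    }
    d_obs[s] = dobs;
    d_rep[s] = drep;
  }
  return List::create(_["observed"] = d_obs, _["simulated"] = d_rep);
}
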