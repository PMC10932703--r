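// Metropolis-within-Gibbs sampler for the zero-inflated lognormal
// state-space abundance model.
//
// Latent abundance is sampled on the log scale (lx = log X), where the
// process and initial terms are Gaussian. Conjugate (Gibbs) updates are
// used for r_j, r_bar and p; adaptive random-walk Metropolis for lx and
// the remaining scalars (adaptation runs during burn-in only and is then
// frozen, so the retained chain is a fixed Markov kernel).
//
// Observations enter pre-classified: only "active" (positive) observations
// carry likelihood terms; zero observations force z = 0 at their
// colony-year and otherwise contribute a constant through the degenerate
// point-mass branch. Sites with positive observations have z forced to 1.
// Consequently every active observation always sits at a z = 1 site and
// the continuous part of the posterior does not depend on the free z's.

#include <Rcpp.h>
using namespace Rcpp;

// hyper layout
enum { H_RBAR = 0, H_SR, H_SP, H_P, H_ALPHA, H_SA,
       H_B1, H_B2, H_B3, H_CV1, H_CV2, H_CV3, H_N };

struct Obs {
  // CSR layout of observations grouped by site (j*Y + y)
  std::vector<int> start;   // size S+1
  std::vector<double> v1;   // aerial: log count; satellite: value S
  std::vector<double> doy;  // centred day of year
  std::vector<int> qual;    // satellite only (0-based), else empty
};

static inline double aerial_term(double logc, double lx, double ad,
                                 double sa) {
  double dev = logc - (lx + ad - 0.5 * sa * sa);
  return -std::log(sa) - 0.5 * dev * dev / (sa * sa);
}

static inline double sat_term(double S, double lx, double ad, double beta,
                              double cv, bool bmean, bool bvar) {
  double mu0 = std::exp(lx + ad);
  double mean = bmean ? beta * mu0 : mu0;
  double sd = (bvar ? beta : 1.0) * mu0 * cv;
  double dev = (S - mean) / sd;
  return -std::log(sd) - 0.5 * dev * dev;
}

static inline double half_normal_lp(double x, double scale) {
  return -0.5 * x * x / (scale * scale);  // up to a constant
}

struct QObs {  // satellite observations of one quality class, flat
  std::vector<int> site;
  std::vector<double> val, doy;
};

struct Sampler {
  int J, Y, S;
  Obs aer, sat;
  QObs satq[3];
  std::vector<int> zf;          // per site: 1 forced present, 0 forced
                                // absent, -1 free
  std::vector<double> lx, r;
  std::vector<int> z;
  double hyper[H_N];
  double lxbar1, slx1;          // fixed empirical initial prior
  // priors
  double r_bar_mean, r_bar_sd, sigma_r_scale, sigma_process_scale,
      sigma_aerial_scale, p_a, p_b, alpha_mean, alpha_sd, log_beta_mean,
      log_beta_sd, cv_scale;
  bool bmean, bvar;
  bool fixed[H_N];
  // adaptation
  std::vector<double> step_lx;
  double step_sc[H_N];          // steps for scalar Metropolis params
  std::vector<int> acc_lx;
  int acc_sc[H_N];
  int batch_len = 50, batch_no = 0;

  double ad_of(const Obs& o, int k) const { return hyper[H_ALPHA] * o.doy[k]; }

  // all likelihood terms touching lx at site s, for a given lx value
  double site_loglik(int s, double lxs) const {
    double ll = 0.0;
    for (int k = aer.start[s]; k < aer.start[s + 1]; ++k)
      ll += aerial_term(aer.v1[k], lxs, hyper[H_ALPHA] * aer.doy[k],
                        hyper[H_SA]);
    for (int k = sat.start[s]; k < sat.start[s + 1]; ++k)
      ll += sat_term(sat.v1[k], lxs, hyper[H_ALPHA] * sat.doy[k],
                     hyper[H_B1 + sat.qual[k]],
                     hyper[H_CV1 + sat.qual[k]], bmean, bvar);
    return ll;
  }

  void update_lx(bool adapt) {
    double sp = hyper[H_SP];
    for (int j = 0; j < J; ++j) {
      double rj = r[j];
      for (int y = 0; y < Y; ++y) {
        int s = j * Y + y;
        double cur = lx[s];
        double prop = cur + norm_rand() * step_lx[s];
        double dlp = 0.0;
        if (y == 0) {
          double d1 = (cur - lxbar1) / slx1, d2 = (prop - lxbar1) / slx1;
          dlp += 0.5 * (d1 * d1 - d2 * d2);
        } else {
          double m = lx[s - 1] + rj;
          double d1 = (cur - m) / sp, d2 = (prop - m) / sp;
          dlp += 0.5 * (d1 * d1 - d2 * d2);
        }
        if (y < Y - 1) {
          double nxt = lx[s + 1];
          double d1 = (nxt - cur - rj) / sp, d2 = (nxt - prop - rj) / sp;
          dlp += 0.5 * (d1 * d1 - d2 * d2);
        }
        if (aer.start[s + 1] > aer.start[s] ||
            sat.start[s + 1] > sat.start[s])
          dlp += site_loglik(s, prop) - site_loglik(s, cur);
        if (std::log(unif_rand()) < dlp) {
          lx[s] = prop;
          if (adapt) ++acc_lx[s];
        }
      }
    }
  }

  void update_z() {
    double p = hyper[H_P];
    for (int s = 0; s < S; ++s) {
      if (zf[s] >= 0) { z[s] = zf[s]; continue; }
      z[s] = (unif_rand() < p) ? 1 : 0;  // no likelihood at unobserved sites
    }
  }

  void update_r() {  // conjugate normal
    double sp2 = hyper[H_SP] * hyper[H_SP];
    double sr2 = hyper[H_SR] * hyper[H_SR];
    for (int j = 0; j < J; ++j) {
      double prec = 1.0 / sr2, mean_num = hyper[H_RBAR] / sr2;
      for (int y = 1; y < Y; ++y) {
        double d = lx[j * Y + y] - lx[j * Y + y - 1];
        prec += 1.0 / sp2;
        mean_num += d / sp2;
      }
      double sd = std::sqrt(1.0 / prec);
      r[j] = mean_num / prec + sd * norm_rand();
    }
  }

  void update_r_bar() {  // conjugate normal
    double sr2 = hyper[H_SR] * hyper[H_SR];
    double prec = J / sr2 + 1.0 / (r_bar_sd * r_bar_sd);
    double num = r_bar_mean / (r_bar_sd * r_bar_sd);
    for (int j = 0; j < J; ++j) num += r[j] / sr2;
    hyper[H_RBAR] = num / prec + std::sqrt(1.0 / prec) * norm_rand();
  }

  void update_p() {  // conjugate beta
    if (fixed[H_P]) return;
    int n1 = 0;
    for (int s = 0; s < S; ++s) n1 += z[s];
    hyper[H_P] = R::rbeta(p_a + n1, p_b + (S - n1));
  }

  double sigma_r_loglik(double srv) const {
    double ll = half_normal_lp(srv, sigma_r_scale);
    for (int j = 0; j < J; ++j) {
      double d = (r[j] - hyper[H_RBAR]) / srv;
      ll += -std::log(srv) - 0.5 * d * d;
    }
    return ll;
  }

  double sigma_p_loglik(double spv) const {
    double ll = half_normal_lp(spv, sigma_process_scale);
    for (int j = 0; j < J; ++j)
      for (int y = 1; y < Y; ++y) {
        double d = (lx[j * Y + y] - lx[j * Y + y - 1] - r[j]) / spv;
        ll += -std::log(spv) - 0.5 * d * d;
      }
    return ll;
  }

  double aerial_loglik(double alpha, double sa) const {
    double ll = 0.0;
    for (int s = 0; s < S; ++s)
      for (int k = aer.start[s]; k < aer.start[s + 1]; ++k)
        ll += aerial_term(aer.v1[k], lx[s], alpha * aer.doy[k], sa);
    return ll;
  }

  double sat_loglik_all(double alpha) const {
    double ll = 0.0;
    for (int q = 0; q < 3; ++q) {
      const QObs& o = satq[q];
      for (size_t k = 0; k < o.val.size(); ++k)
        ll += sat_term(o.val[k], lx[o.site[k]], alpha * o.doy[k],
                       hyper[H_B1 + q], hyper[H_CV1 + q], bmean, bvar);
    }
    return ll;
  }

  double sat_loglik_q(int q, double beta, double cv) const {
    double ll = 0.0;
    const QObs& o = satq[q];
    for (size_t k = 0; k < o.val.size(); ++k)
      ll += sat_term(o.val[k], lx[o.site[k]], hyper[H_ALPHA] * o.doy[k],
                     beta, cv, bmean, bvar);
    return ll;
  }

  // generic log-scale RW Metropolis for a positive scalar; target(x)
  // supplied on the natural scale, Jacobian included in the ratio.
  template <typename F>
  void mh_log_scale(int h, F target, bool adapt) {
    if (fixed[h]) return;
    double cur = hyper[h];
    double prop = cur * std::exp(norm_rand() * step_sc[h]);
    double dlp = target(prop) - target(cur) + std::log(prop / cur);
    if (std::log(unif_rand()) < dlp) {
      hyper[h] = prop;
      if (adapt) ++acc_sc[h];
    }
  }

  void update_scalars(bool adapt) {
    // alpha: natural-scale RW
    if (!fixed[H_ALPHA]) {
      double cur = hyper[H_ALPHA];
      double prop = cur + norm_rand() * step_sc[H_ALPHA];
      double da = (cur - alpha_mean) / alpha_sd,
             db = (prop - alpha_mean) / alpha_sd;
      double dlp = 0.5 * (da * da - db * db) +
                   (aerial_loglik(prop, hyper[H_SA]) + sat_loglik_all(prop)) -
                   (aerial_loglik(cur, hyper[H_SA]) + sat_loglik_all(cur));
      if (std::log(unif_rand()) < dlp) {
        hyper[H_ALPHA] = prop;
        if (adapt) ++acc_sc[H_ALPHA];
      }
    }
    mh_log_scale(H_SR, [&](double v) { return sigma_r_loglik(v); }, adapt);
    mh_log_scale(H_SP, [&](double v) { return sigma_p_loglik(v); }, adapt);
    mh_log_scale(H_SA,
                 [&](double v) {
                   return half_normal_lp(v, sigma_aerial_scale) +
                          aerial_loglik(hyper[H_ALPHA], v);
                 },
                 adapt);
    for (int q = 0; q < 3; ++q) {
      mh_log_scale(H_B1 + q,
                   [&](double v) {
                     double lb = std::log(v) - log_beta_mean;
                     return -std::log(v) -
                            0.5 * lb * lb / (log_beta_sd * log_beta_sd) +
                            sat_loglik_q(q, v, hyper[H_CV1 + q]);
                   },
                   adapt);
      mh_log_scale(H_CV1 + q,
                   [&](double v) {
                     return half_normal_lp(v, cv_scale) +
                            sat_loglik_q(q, hyper[H_B1 + q], v);
                   },
                   adapt);
    }
  }

  void adapt_batch() {
    ++batch_no;
    double delta = std::min(0.1, 1.0 / std::sqrt((double)batch_no));
    for (int s = 0; s < S; ++s) {
      double rate = (double)acc_lx[s] / batch_len;
      step_lx[s] *= std::exp(rate > 0.44 ? delta : -delta);
      step_lx[s] = std::min(std::max(step_lx[s], 1e-6), 10.0);
      acc_lx[s] = 0;
    }
    for (int h = 0; h < H_N; ++h) {
      double rate = (double)acc_sc[h] / batch_len;
      step_sc[h] *= std::exp(rate > 0.44 ? delta : -delta);
      step_sc[h] = std::min(std::max(step_sc[h], 1e-8), 10.0);
      acc_sc[h] = 0;
    }
  }

  void sweep(bool adapt) {
    update_lx(adapt);
    update_z();
    update_r();
    update_r_bar();
    update_p();
    update_scalars(adapt);
  }
};

static Obs make_obs(int S, const IntegerVector& site,
                    const NumericVector& v1, const NumericVector& doy,
                    const IntegerVector& qual) {
  Obs o;
  int n = site.size();
  o.start.assign(S + 1, 0);
  for (int i = 0; i < n; ++i) o.start[site[i] + 1]++;
  for (int s = 0; s < S; ++s) o.start[s + 1] += o.start[s];
  std::vector<int> pos(o.start.begin(), o.start.end() - 1);
  o.v1.resize(n);
  o.doy.resize(n);
  o.qual.resize(qual.size() ? n : 0);
  for (int i = 0; i < n; ++i) {
    int k = pos[site[i]]++;
    o.v1[k] = v1[i];
    o.doy[k] = doy[i];
    if (qual.size()) o.qual[k] = qual[i];
  }
  return o;
}

// [[Rcpp::export(name = ".mcmc_chain")]]
List mcmc_chain(int J, int Y, IntegerVector a_site, NumericVector a_logc,
                NumericVector a_doy, IntegerVector s_site,
                NumericVector s_val, NumericVector s_doy,
                IntegerVector s_qual, IntegerVector z_forced,
                NumericVector lx0, IntegerVector z0, NumericVector r0,
                NumericVector hyper0, NumericVector fixed_mask,
                double lxbar1, double slx1, List prior, int burn_in,
                int thin, int n_store) {
  Sampler sm;
  sm.J = J;
  sm.Y = Y;
  sm.S = J * Y;
  sm.aer = make_obs(sm.S, a_site, a_logc, a_doy, IntegerVector(0));
  sm.sat = make_obs(sm.S, s_site, s_val, s_doy, s_qual);
  for (int i = 0; i < s_site.size(); ++i) {
    QObs& o = sm.satq[s_qual[i]];
    o.site.push_back(s_site[i]);
    o.val.push_back(s_val[i]);
    o.doy.push_back(s_doy[i]);
  }
  sm.zf.assign(z_forced.begin(), z_forced.end());
  sm.lx.assign(lx0.begin(), lx0.end());
  sm.z.assign(z0.begin(), z0.end());
  sm.r.assign(r0.begin(), r0.end());
  for (int h = 0; h < H_N; ++h) {
    sm.hyper[h] = hyper0[h];
    sm.fixed[h] = fixed_mask[h] != 0;
    sm.step_sc[h] = 0.1;
    sm.acc_sc[h] = 0;
  }
  sm.step_sc[H_ALPHA] = 0.01;
  sm.lxbar1 = lxbar1;
  sm.slx1 = slx1;
  sm.r_bar_mean = prior["r_bar_mean"];
  sm.r_bar_sd = prior["r_bar_sd"];
  sm.sigma_r_scale = prior["sigma_r_scale"];
  sm.sigma_process_scale = prior["sigma_process_scale"];
  sm.sigma_aerial_scale = prior["sigma_aerial_scale"];
  sm.p_a = prior["p_a"];
  sm.p_b = prior["p_b"];
  sm.alpha_mean = prior["alpha_mean"];
  sm.alpha_sd = prior["alpha_sd"];
  sm.log_beta_mean = prior["log_beta_mean"];
  sm.log_beta_sd = prior["log_beta_sd"];
  sm.cv_scale = prior["cv_scale"];
  sm.bmean = prior["beta_in_mean"];
  sm.bvar = prior["beta_in_variance"];
  sm.step_lx.assign(sm.S, 0.2);
  sm.acc_lx.assign(sm.S, 0);

  NumericMatrix hyper_draws(n_store, H_N);
  NumericMatrix r_draws(n_store, J);
  NumericMatrix X_draws(n_store, sm.S);
  IntegerMatrix z_draws(n_store, sm.S);

  RNGScope scope;
  int it = 0;
  for (; it < burn_in; ++it) {
    sm.sweep(true);
    if ((it + 1) % sm.batch_len == 0) sm.adapt_batch();
  }
  for (int d = 0; d < n_store; ++d) {
    for (int t = 0; t < thin; ++t) sm.sweep(false);
    for (int h = 0; h < H_N; ++h) hyper_draws(d, h) = sm.hyper[h];
    for (int j = 0; j < J; ++j) r_draws(d, j) = sm.r[j];
    for (int s = 0; s < sm.S; ++s) {
      X_draws(d, s) = std::exp(sm.lx[s]);
      z_draws(d, s) = sm.z[s];
    }
    if (d % 256 == 0) Rcpp::checkUserInterrupt();
  }
  NumericVector steps(sm.S);
  for (int s = 0; s < sm.S; ++s) steps[s] = sm.step_lx[s];
  return List::create(_["hyper"] = hyper_draws, _["r"] = r_draws,
                      _["X"] = X_draws, _["z"] = z_draws,
                      _["step_lx"] = steps);
}
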