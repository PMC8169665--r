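#include <Rcpp.h>
#include <vector>
#include "wfpt.h"
using namespace Rcpp;

// Adaptive Metropolis-within-Gibbs sampler for the hierarchical diffusion
// model. Per-trial likelihood (beta fixed at 0.5, s = 1):
//
//   rt_pj | alpha_p, nu_pi, theta_pi, eta, chi
//     with trial drift  ~ N(nu_pi, eta^2)   marginalised in closed form
//     and trial nondec. ~ N(theta_pi, chi^2) integrated by Gauss-Hermite
//     quadrature (nodes clamped at 0)
//
// Hierarchy: nu_pi ~ N(mu_nu[i], sigma_nu^2); theta_pi ~ N(mu_theta[i],
// sigma_theta^2) constrained >= 0; alpha_p ~ N(mu_alpha, sigma_alpha^2)
// constrained > 0 (truncation mass is negligible at the scales of interest
// and is ignored in the hierarchy densities; the constraints are enforced
// on the person-level parameters themselves).
//
// Updates per sweep: random-walk Metropolis for person-level parameters and
// the trial-level spreads (log scale), exact conjugate Gibbs draws for the
// group-level means, random-walk Metropolis on the log of the group-level
// SDs. Proposal scales adapt towards a 0.44 acceptance rate during the
// adaptation phase and are frozen afterwards.
//
// Group-mean priors: mu_nu[i] ~ N(m_nu, s_nu^2); mu_theta[i] ~ N(m_th,
// s_th^2) kept >= 0; mu_alpha ~ N(m_al, s_al^2) kept > 0. SD priors:
// half-Normal(0, scale) on sigma_nu, sigma_theta, sigma_alpha, eta, chi.

static const double LOG_FLOOR = 1e-300;

struct HdmData {
  std::vector<double> rt;
  std::vector<int> upper, pidx, cidx;
  int P, C, n;
  std::vector<std::vector<int>> cell_trials;   // [p*C + i] -> trial ids
  std::vector<std::vector<int>> person_trials; // [p] -> trial ids
};

struct GH {
  std::vector<double> x, w;
  int K;
};

class HdmSampler {
public:
  HdmData d;
  GH gh;
  double eps;
  // state
  std::vector<double> mu_nu, mu_theta;        // [C]
  double sigma_nu, sigma_theta, mu_alpha, sigma_alpha, eta, chi;
  std::vector<double> alpha;                  // [P]
  std::vector<double> nu, theta;              // [P*C]
  // caches: per trial x node, f0/(a^2) and decision time u for current state
  std::vector<double> f0c, uc;                // [n*K]
  std::vector<double> cell_ll;                // [P*C]
  // scratch for proposals
  std::vector<double> f0s, us;
  // priors
  double m_nu, s_nu, m_th, s_th, m_al, s_al;
  double sc_signu, sc_sigth, sc_sigal, sc_eta, sc_chi;
  bool fix_eta, fix_chi;
  // adaptive proposal scales
  std::vector<double> sc_nu, sc_theta, sc_alpha; // per parameter
  std::vector<double> sc_shift_nu, sc_shift_theta; // per condition
  double sc_shift_alpha;
  double sc_lsnu, sc_lsth, sc_lsal, sc_leta, sc_lchi;
  double acc_nu = 0, acc_theta = 0, acc_alpha = 0; long try_nu = 0, try_theta = 0, try_alpha = 0;

  double trial_dens_full(int t, double a, double th, double ch,
                         double mu, double et, double* f0out, double* uout) {
    double b = a * 0.5, a2 = a * a;
    double m = d.upper[t] ? -mu : mu;
    double dens = 0.0;
    for (int k = 0; k < gh.K; ++k) {
      double tk = th + ch * gh.x[k];
      if (tk < 0.0) tk = 0.0;
      double u = d.rt[t] - tk;
      double f0 = (u > 0.0) ? wfpt_f0(u / a2, 0.5, eps, 0) / a2 : 0.0;
      f0out[k] = f0; uout[k] = u;
      if (f0 > 0.0) dens += gh.w[k] * wfpt_marg_factor(u, m, et, b) * f0;
    }
    if (!std::isfinite(dens) || dens < 0.0) dens = 0.0;
    return dens;
  }

  double trial_dens_cached(int t, double a, double mu, double et) {
    double b = a * 0.5;
    double m = d.upper[t] ? -mu : mu;
    double dens = 0.0;
    const double* f0 = &f0c[(size_t)t * gh.K];
    const double* u = &uc[(size_t)t * gh.K];
    for (int k = 0; k < gh.K; ++k)
      if (f0[k] > 0.0) dens += gh.w[k] * wfpt_marg_factor(u[k], m, et, b) * f0[k];
    if (!std::isfinite(dens) || dens < 0.0) dens = 0.0;
    return dens;
  }

  // full recompute of one cell into scratch; returns log-lik
  double cell_ll_full(int p, int i, double a, double th, double ch,
                      double mu, double et) {
    const std::vector<int>& tr = d.cell_trials[p * d.C + i];
    double ll = 0.0;
    for (size_t j = 0; j < tr.size(); ++j) {
      int t = tr[j];
      double dens = trial_dens_full(t, a, th, ch, mu, et,
                                    &f0s[(size_t)t * gh.K], &us[(size_t)t * gh.K]);
      ll += std::log(std::max(dens, LOG_FLOOR));
    }
    return ll;
  }

  double cell_ll_cached(int p, int i, double a, double mu, double et) {
    const std::vector<int>& tr = d.cell_trials[p * d.C + i];
    double ll = 0.0;
    for (size_t j = 0; j < tr.size(); ++j)
      ll += std::log(std::max(trial_dens_cached(tr[j], a, mu, et), LOG_FLOOR));
    return ll;
  }

  void commit_scratch_cell(int p, int i) {
    const std::vector<int>& tr = d.cell_trials[p * d.C + i];
    for (size_t j = 0; j < tr.size(); ++j) {
      int t = tr[j];
      for (int k = 0; k < gh.K; ++k) {
        f0c[(size_t)t * gh.K + k] = f0s[(size_t)t * gh.K + k];
        uc[(size_t)t * gh.K + k] = us[(size_t)t * gh.K + k];
      }
    }
  }

  void refresh_all_caches() {
    for (int p = 0; p < d.P; ++p)
      for (int i = 0; i < d.C; ++i) {
        cell_ll[p * d.C + i] = cell_ll_full(p, i, alpha[p], theta[p * d.C + i],
                                            chi, nu[p * d.C + i], eta);
        commit_scratch_cell(p, i);
      }
  }

  static double dnorm_log(double x, double m, double s) {
    double z = (x - m) / s;
    return -0.5 * z * z - std::log(s);
  }

  void adapt(double& scale, double acc_prob, double gamma) {
    scale *= std::exp(gamma * (acc_prob - 0.44));
    if (scale < 1e-6) scale = 1e-6;
    if (scale > 50.0) scale = 50.0;
  }

  void sweep(bool adapting, double gamma) {
    // 1. nu_pi: drift factor only, f0 cache reused
    for (int p = 0; p < d.P; ++p)
      for (int i = 0; i < d.C; ++i) {
        int pi = p * d.C + i;
        double cur = nu[pi];
        double prop = cur + sc_nu[pi] * norm_rand();
        double llp = cell_ll_cached(p, i, alpha[p], prop, eta);
        double lr = llp - cell_ll[pi] +
          dnorm_log(prop, mu_nu[i], sigma_nu) - dnorm_log(cur, mu_nu[i], sigma_nu);
        double ap = std::min(1.0, std::exp(lr));
        ++try_nu;
        if (unif_rand() < ap) { nu[pi] = prop; cell_ll[pi] = llp; acc_nu += 1; }
        if (adapting) adapt(sc_nu[pi], ap, gamma);
      }
    // 2. theta_pi: full recompute (u changes)
    for (int p = 0; p < d.P; ++p)
      for (int i = 0; i < d.C; ++i) {
        int pi = p * d.C + i;
        double cur = theta[pi];
        double prop = cur + sc_theta[pi] * norm_rand();
        double ap = 0.0;
        ++try_theta;
        if (prop >= 0.0) {
          double llp = cell_ll_full(p, i, alpha[p], prop, chi, nu[pi], eta);
          double lr = llp - cell_ll[pi] +
            dnorm_log(prop, mu_theta[i], sigma_theta) -
            dnorm_log(cur, mu_theta[i], sigma_theta);
          ap = std::min(1.0, std::exp(lr));
          if (unif_rand() < ap) {
            theta[pi] = prop; cell_ll[pi] = llp; commit_scratch_cell(p, i);
            acc_theta += 1;
          }
        }
        if (adapting) adapt(sc_theta[pi], ap, gamma);
      }
    // 3. alpha_p: full recompute over the participant's cells
    for (int p = 0; p < d.P; ++p) {
      double cur = alpha[p];
      double prop = cur + sc_alpha[p] * norm_rand();
      double ap = 0.0;
      ++try_alpha;
      if (prop > 0.05) {
        double llc = 0.0;
        std::vector<double> llp_cell(d.C);
        double llp = 0.0;
        for (int i = 0; i < d.C; ++i) {
          llp_cell[i] = cell_ll_full(p, i, prop, theta[p * d.C + i], chi,
                                     nu[p * d.C + i], eta);
          llp += llp_cell[i];
          llc += cell_ll[p * d.C + i];
        }
        double lr = llp - llc +
          dnorm_log(prop, mu_alpha, sigma_alpha) -
          dnorm_log(cur, mu_alpha, sigma_alpha);
        ap = std::min(1.0, std::exp(lr));
        if (unif_rand() < ap) {
          alpha[p] = prop; acc_alpha += 1;
          for (int i = 0; i < d.C; ++i) {
            cell_ll[p * d.C + i] = llp_cell[i];
            commit_scratch_cell(p, i);
          }
        }
      }
      if (adapting) adapt(sc_alpha[p], ap, gamma);
    }
    // 4. conjugate Gibbs for group means
    for (int i = 0; i < d.C; ++i) {
      double sum = 0.0;
      for (int p = 0; p < d.P; ++p) sum += nu[p * d.C + i];
      double prec = d.P / (sigma_nu * sigma_nu) + 1.0 / (s_nu * s_nu);
      double mean = (sum / (sigma_nu * sigma_nu) + m_nu / (s_nu * s_nu)) / prec;
      mu_nu[i] = mean + norm_rand() / std::sqrt(prec);
    }
    for (int i = 0; i < d.C; ++i) {
      double sum = 0.0;
      for (int p = 0; p < d.P; ++p) sum += theta[p * d.C + i];
      double prec = d.P / (sigma_theta * sigma_theta) + 1.0 / (s_th * s_th);
      double mean = (sum / (sigma_theta * sigma_theta) + m_th / (s_th * s_th)) / prec;
      double draw;
      int tries = 0;
      do { draw = mean + norm_rand() / std::sqrt(prec); } while (draw < 0.0 && ++tries < 100);
      mu_theta[i] = std::max(draw, 0.0);
    }
    {
      double sum = 0.0;
      for (int p = 0; p < d.P; ++p) sum += alpha[p];
      double prec = d.P / (sigma_alpha * sigma_alpha) + 1.0 / (s_al * s_al);
      double mean = (sum / (sigma_alpha * sigma_alpha) + m_al / (s_al * s_al)) / prec;
      double draw;
      int tries = 0;
      do { draw = mean + norm_rand() / std::sqrt(prec); } while (draw <= 0.0 && ++tries < 100);
      mu_alpha = std::max(draw, 1e-8);
    }
    // 4b. joint shift moves: translate a condition's group mean together
    // with all its person-level parameters. The centred hierarchy couples
    // them (tightly when the group SD is small), so single-site updates
    // alone mix the group level arbitrarily slowly.
    for (int i = 0; i < d.C; ++i) {
      double s = sc_shift_nu[i] * norm_rand();
      double llp = 0.0, llc = 0.0;
      for (int p = 0; p < d.P; ++p) {
        llp += cell_ll_cached(p, i, alpha[p], nu[p * d.C + i] + s, eta);
        llc += cell_ll[p * d.C + i];
      }
      double lr = llp - llc +
        dnorm_log(mu_nu[i] + s, m_nu, s_nu) - dnorm_log(mu_nu[i], m_nu, s_nu);
      double ap = std::min(1.0, std::exp(lr));
      if (unif_rand() < ap) {
        mu_nu[i] += s;
        for (int p = 0; p < d.P; ++p) {
          nu[p * d.C + i] += s;
          cell_ll[p * d.C + i] = cell_ll_cached(p, i, alpha[p], nu[p * d.C + i], eta);
        }
      }
      if (adapting) adapt(sc_shift_nu[i], ap, gamma);
    }
    for (int i = 0; i < d.C; ++i) {
      double s = sc_shift_theta[i] * norm_rand();
      double ap = 0.0;
      bool ok = mu_theta[i] + s >= 0.0;
      for (int p = 0; ok && p < d.P; ++p)
        if (theta[p * d.C + i] + s < 0.0) ok = false;
      if (ok) {
        double llp = 0.0, llc = 0.0;
        for (int p = 0; p < d.P; ++p) {
          llp += cell_ll_full(p, i, alpha[p], theta[p * d.C + i] + s, chi,
                              nu[p * d.C + i], eta);
          llc += cell_ll[p * d.C + i];
        }
        double lr = llp - llc +
          dnorm_log(mu_theta[i] + s, m_th, s_th) -
          dnorm_log(mu_theta[i], m_th, s_th);
        ap = std::min(1.0, std::exp(lr));
        if (unif_rand() < ap) {
          mu_theta[i] += s;
          for (int p = 0; p < d.P; ++p) {
            theta[p * d.C + i] += s;
            cell_ll[p * d.C + i] = cell_ll_full(p, i, alpha[p],
                                                theta[p * d.C + i], chi,
                                                nu[p * d.C + i], eta);
            commit_scratch_cell(p, i);
          }
        }
      }
      if (adapting) adapt(sc_shift_theta[i], ap, gamma);
    }
    {
      double s = sc_shift_alpha * norm_rand();
      double ap = 0.0;
      bool ok = mu_alpha + s > 0.0;
      for (int p = 0; ok && p < d.P; ++p)
        if (alpha[p] + s <= 0.05) ok = false;
      if (ok) {
        double llp = 0.0, llc = 0.0;
        std::vector<double> llp_cell(d.P * d.C);
        for (int p = 0; p < d.P; ++p)
          for (int i = 0; i < d.C; ++i) {
            llp_cell[p * d.C + i] = cell_ll_full(p, i, alpha[p] + s,
                                                 theta[p * d.C + i], chi,
                                                 nu[p * d.C + i], eta);
            llp += llp_cell[p * d.C + i];
            llc += cell_ll[p * d.C + i];
          }
        double lr = llp - llc +
          dnorm_log(mu_alpha + s, m_al, s_al) - dnorm_log(mu_alpha, m_al, s_al);
        ap = std::min(1.0, std::exp(lr));
        if (unif_rand() < ap) {
          mu_alpha += s;
          for (int p = 0; p < d.P; ++p) alpha[p] += s;
          for (int j = 0; j < d.P * d.C; ++j) cell_ll[j] = llp_cell[j];
          for (int p = 0; p < d.P; ++p)
            for (int i = 0; i < d.C; ++i) commit_scratch_cell(p, i);
        }
      }
      if (adapting) adapt(sc_shift_alpha, ap, gamma);
    }
    // 5. group SDs: slice sampling on the log scale (hierarchy terms only,
    // so evaluations are cheap; slice moves avoid the slow random-walk
    // mixing of scale parameters near the bottom of the funnel)
    sigma_nu = slice_sigma(sigma_nu, sc_signu, [&](double s) {
      double ll = 0.0;
      for (int p = 0; p < d.P; ++p)
        for (int i = 0; i < d.C; ++i)
          ll += dnorm_log(nu[p * d.C + i], mu_nu[i], s);
      return ll;
    });
    sigma_theta = slice_sigma(sigma_theta, sc_sigth, [&](double s) {
      double ll = 0.0;
      for (int p = 0; p < d.P; ++p)
        for (int i = 0; i < d.C; ++i)
          ll += dnorm_log(theta[p * d.C + i], mu_theta[i], s);
      return ll;
    });
    sigma_alpha = slice_sigma(sigma_alpha, sc_sigal, [&](double s) {
      double ll = 0.0;
      for (int p = 0; p < d.P; ++p) ll += dnorm_log(alpha[p], mu_alpha, s);
      return ll;
    });
    // 6. trial-level spreads (data likelihood over all trials)
    if (!fix_eta) {
      double cur = eta;
      double prop = cur * std::exp(sc_leta * norm_rand());
      double llp = 0.0, llc = 0.0;
      for (int p = 0; p < d.P; ++p)
        for (int i = 0; i < d.C; ++i) {
          llp += cell_ll_cached(p, i, alpha[p], nu[p * d.C + i], prop);
          llc += cell_ll[p * d.C + i];
        }
      double lr = llp - llc - (prop * prop - cur * cur) / (2.0 * sc_eta * sc_eta) +
        std::log(prop) - std::log(cur);
      double ap = std::min(1.0, std::exp(lr));
      if (unif_rand() < ap) {
        eta = prop;
        for (int p = 0; p < d.P; ++p)
          for (int i = 0; i < d.C; ++i)
            cell_ll[p * d.C + i] = cell_ll_cached(p, i, alpha[p], nu[p * d.C + i], eta);
      }
      if (adapting) adapt(sc_leta, ap, gamma);
    }
    if (!fix_chi) {
      double cur = chi;
      double prop = cur * std::exp(sc_lchi * norm_rand());
      double llp = 0.0, llc = 0.0;
      std::vector<double> llp_cell(d.P * d.C);
      for (int p = 0; p < d.P; ++p)
        for (int i = 0; i < d.C; ++i) {
          llp_cell[p * d.C + i] = cell_ll_full(p, i, alpha[p], theta[p * d.C + i],
                                               prop, nu[p * d.C + i], eta);
          llp += llp_cell[p * d.C + i];
          llc += cell_ll[p * d.C + i];
        }
      double lr = llp - llc - (prop * prop - cur * cur) / (2.0 * sc_chi * sc_chi) +
        std::log(prop) - std::log(cur);
      double ap = std::min(1.0, std::exp(lr));
      if (unif_rand() < ap) {
        chi = prop;
        for (int p = 0; p < d.P; ++p)
          for (int i = 0; i < d.C; ++i) {
            cell_ll[p * d.C + i] = llp_cell[p * d.C + i];
            commit_scratch_cell(p, i);
          }
      }
      if (adapting) adapt(sc_lchi, ap, gamma);
    }
  }

  // stepping-out slice sampler on x = log(sigma); the target over x is
  // loglik(sigma) - sigma^2/(2 scale^2) + x (half-normal prior + Jacobian)
  template <typename F>
  double slice_sigma(double cur, double prior_scale, F loglik) {
    auto lt = [&](double x) {
      double s = std::exp(x);
      return loglik(s) - s * s / (2.0 * prior_scale * prior_scale) + x;
    };
    double x0 = std::log(cur);
    double ly = lt(x0) + std::log(unif_rand());
    double w = 0.5;
    double L = x0 - w * unif_rand(), R = L + w;
    int m = 50;
    while (m-- > 0 && lt(L) > ly) L -= w;
    m = 50;
    while (m-- > 0 && lt(R) > ly) R += w;
    for (int it = 0; it < 100; ++it) {
      double x1 = L + unif_rand() * (R - L);
      if (lt(x1) > ly) return std::exp(x1);
      if (x1 < x0) L = x1; else R = x1;
    }
    return cur;
  }
};

// [[Rcpp::export(name = ".hdm_chain_cpp")]]
List hdm_chain_cpp(NumericVector rt, IntegerVector upper, IntegerVector pidx,
                   IntegerVector cidx, int P, int C,
                   NumericVector init, List prior, List control) {
  HdmSampler S;
  S.d.rt = as<std::vector<double>>(rt);
  S.d.upper = as<std::vector<int>>(upper);
  S.d.pidx = as<std::vector<int>>(pidx);
  S.d.cidx = as<std::vector<int>>(cidx);
  S.d.P = P; S.d.C = C; S.d.n = rt.size();
  S.d.cell_trials.assign(P * C, {});
  S.d.person_trials.assign(P, {});
  for (int t = 0; t < S.d.n; ++t) {
    S.d.cell_trials[S.d.pidx[t] * C + S.d.cidx[t]].push_back(t);
    S.d.person_trials[S.d.pidx[t]].push_back(t);
  }
  S.gh.x = as<std::vector<double>>(control["gh_x"]);
  S.gh.w = as<std::vector<double>>(control["gh_w"]);
  S.gh.K = S.gh.x.size();
  S.eps = as<double>(control["eps"]);
  S.fix_eta = as<bool>(control["fix_eta"]);
  S.fix_chi = as<bool>(control["fix_chi"]);
  int n_burn = as<int>(control["burn_in"]);
  int n_adapt = as<int>(control["adapt"]);
  int n_keep = as<int>(control["draws"]);
  int thin = as<int>(control["thin"]);

  S.m_nu = as<double>(prior["mu_nu_mean"]);   S.s_nu = as<double>(prior["mu_nu_sd"]);
  S.m_th = as<double>(prior["mu_theta_mean"]); S.s_th = as<double>(prior["mu_theta_sd"]);
  S.m_al = as<double>(prior["mu_alpha_mean"]); S.s_al = as<double>(prior["mu_alpha_sd"]);
  S.sc_signu = as<double>(prior["sigma_nu_scale"]);
  S.sc_sigth = as<double>(prior["sigma_theta_scale"]);
  S.sc_sigal = as<double>(prior["sigma_alpha_scale"]);
  S.sc_eta = as<double>(prior["eta_scale"]);
  S.sc_chi = as<double>(prior["chi_scale"]);

  // unpack init: mu_nu[C], mu_theta[C], sigma_nu, sigma_theta, mu_alpha,
  // sigma_alpha, eta, chi, alpha[P], nu[P*C], theta[P*C]
  int off = 0;
  S.mu_nu.assign(init.begin(), init.begin() + C); off += C;
  S.mu_theta.assign(init.begin() + off, init.begin() + off + C); off += C;
  S.sigma_nu = init[off++]; S.sigma_theta = init[off++];
  S.mu_alpha = init[off++]; S.sigma_alpha = init[off++];
  S.eta = init[off++]; S.chi = init[off++];
  S.alpha.assign(init.begin() + off, init.begin() + off + P); off += P;
  S.nu.assign(init.begin() + off, init.begin() + off + P * C); off += P * C;
  S.theta.assign(init.begin() + off, init.begin() + off + P * C);

  S.f0c.assign((size_t)S.d.n * S.gh.K, 0.0);
  S.uc.assign((size_t)S.d.n * S.gh.K, 0.0);
  S.f0s = S.f0c; S.us = S.uc;
  S.cell_ll.assign(P * C, 0.0);

  S.sc_nu.assign(P * C, 0.25);
  S.sc_theta.assign(P * C, 0.02);
  S.sc_alpha.assign(P, 0.12);
  S.sc_shift_nu.assign(C, 0.15);
  S.sc_shift_theta.assign(C, 0.01);
  S.sc_shift_alpha = 0.08;
  S.sc_lsnu = S.sc_lsth = S.sc_lsal = 0.3;
  S.sc_leta = S.sc_lchi = 0.15;

  S.refresh_all_caches();
  double ll0 = 0.0;
  for (int j = 0; j < P * C; ++j) ll0 += S.cell_ll[j];
  if (!R_finite(ll0))
    stop("log-likelihood not finite at the initial values");

  int npar = 2 * C + 6 + P + 2 * P * C;
  NumericMatrix draws(n_keep, npar);
  int total = n_burn + n_keep * thin;
  for (int it = 0; it < total; ++it) {
    bool adapting = it < n_adapt;
    double gamma = adapting ? std::min(0.25, 2.0 / std::pow(it + 10.0, 0.6)) : 0.0;
    S.sweep(adapting, gamma);
    if (it >= n_burn && ((it - n_burn + 1) % thin == 0)) {
      int row = (it - n_burn) / thin;
      int c0 = 0;
      for (int i = 0; i < C; ++i) draws(row, c0++) = S.mu_nu[i];
      for (int i = 0; i < C; ++i) draws(row, c0++) = S.mu_theta[i];
      draws(row, c0++) = S.sigma_nu; draws(row, c0++) = S.sigma_theta;
      draws(row, c0++) = S.mu_alpha; draws(row, c0++) = S.sigma_alpha;
      draws(row, c0++) = S.eta; draws(row, c0++) = S.chi;
      for (int p = 0; p < P; ++p) draws(row, c0++) = S.alpha[p];
      for (int j = 0; j < P * C; ++j) draws(row, c0++) = S.nu[j];
      for (int j = 0; j < P * C; ++j) draws(row, c0++) = S.theta[j];
    }
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
    _["draws"] = draws,
    _["accept"] = NumericVector::create(
      _["nu"] = S.acc_nu / std::max(1L, S.try_nu),
      _["theta"] = S.acc_theta / std::max(1L, S.try_theta),
      _["alpha"] = S.acc_alpha / std::max(1L, S.try_alpha)));
}

// Total marginal data log-likelihood for a full parameter vector, used to
// audit the sampler's target against the R-side log-posterior definition.
// [[Rcpp::export(name = ".hdm_loglik_cpp")]]
double hdm_loglik_cpp(NumericVector rt, IntegerVector upper, IntegerVector pidx,
                      IntegerVector cidx, int P, int C,
                      NumericVector alpha, NumericVector nu, NumericVector theta,
                      double eta, double chi,
                      NumericVector gh_x, NumericVector gh_w, double eps) {
  int n = rt.size(), K = gh_x.size();
  double ll = 0.0;
  for (int t = 0; t < n; ++t) {
    int p = pidx[t], i = cidx[t];
    double a = alpha[p], a2 = a * a, b = a * 0.5;
    double mu = nu[p * C + i];
    double m = upper[t] ? -mu : mu;
    double dens = 0.0;
    for (int k = 0; k < K; ++k) {
      double tk = theta[p * C + i] + chi * gh_x[k];
      if (tk < 0.0) tk = 0.0;
      double u = rt[t] - tk;
      if (u > 0.0)
        dens += gh_w[k] * wfpt_marg_factor(u, m, eta, b) *
                wfpt_f0(u / a2, 0.5, eps, 0) / a2;
    }
    ll += std::log(std::max(dens, LOG_FLOOR));
  }
  return ll;
}
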