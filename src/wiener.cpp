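#include <Rcpp.h>
#include "rng.h"
#include "wfpt.h"
using namespace Rcpp;

// Wiener first-passage-time machinery. Time is in seconds, the within-trial
// diffusion coefficient is fixed at s = 1, and densities are "defective":
// the density for one boundary integrates to that boundary's absorption
// probability, and upper + lower integrate to 1.

// Density of hitting the *lower* boundary at decision time u, drift v,
// boundary separation a, relative start w.
static double wfpt_lower(double u, double v, double a, double w,
                         double eps, int method) {
  if (u <= 0.0) return 0.0;
  double tt = u / (a * a);
  double f = wfpt_f0(tt, w, eps, method);
  return std::exp(-v * a * w - v * v * u / 2.0) / (a * a) * f;
}

// [[Rcpp::export(name = ".dwiener_cpp")]]
NumericVector dwiener_cpp(NumericVector t, double alpha, double beta,
                          double delta, double tau,
                          LogicalVector upper, double eps, int method) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double u = t[i] - tau;
    if (u <= 0.0 || !R_finite(t[i])) { out[i] = 0.0; continue; }
    if (upper[i]) {
      out[i] = wfpt_lower(u, -delta, alpha, 1.0 - beta, eps, method);
    } else {
      out[i] = wfpt_lower(u, delta, alpha, beta, eps, method);
    }
  }
  return out;
}

// [[Rcpp::export(name = ".dwiener_marg_cpp")]]
NumericVector dwiener_marg_cpp(NumericVector t, double alpha, double mu,
                               double eta, double theta, double chi,
                               LogicalVector upper, NumericVector gh_x,
                               NumericVector gh_w, double eps) {
  // density with drift ~ N(mu, eta^2) marginalised analytically and
  // nondecision ~ N(theta, chi^2) integrated by Gauss-Hermite quadrature
  // (nodes clamped at 0; beta fixed at 0.5)
  int n = t.size(), K = gh_x.size();
  NumericVector out(n);
  double b = alpha * 0.5;
  for (int i = 0; i < n; ++i) {
    double m = upper[i] ? -mu : mu;
    double dens = 0.0;
    for (int k = 0; k < K; ++k) {
      double tk = theta + chi * gh_x[k];
      if (tk < 0.0) tk = 0.0;
      double u = t[i] - tk;
      if (u > 0.0) {
        double f0 = wfpt_f0(u / (alpha * alpha), 0.5, eps, 0);
        dens += gh_w[k] * wfpt_marg_factor(u, m, eta, b) * f0 / (alpha * alpha);
      }
    }
    out[i] = dens;
  }
  return out;
}

// [[Rcpp::export(name = ".rwiener_cpp")]]
List rwiener_cpp(int n, NumericVector alpha, NumericVector beta,
                 NumericVector delta, NumericVector tau,
                 double dt, double seed) {
  // Euler-Maruyama first-passage simulation with the Broadie-Glasserman-Kou
  // continuity correction: discrete monitoring detects crossings late, which
  // is equivalent (to leading order) to boundaries further out by
  // 0.5826*s*sqrt(dt); simulating against boundaries shifted inward by that
  // amount cancels the bias. Parameter vectors are recycled over trials.
  NumericVector rt(n);
  IntegerVector up(n);
  Xoshiro rng((uint64_t)seed);
  double sdt = std::sqrt(dt);
  double shift = 0.5826 * sdt;
  int na = alpha.size(), nb = beta.size(), nd = delta.size(), nt = tau.size();
  for (int i = 0; i < n; ++i) {
    double a = alpha[i % na], b = beta[i % nb], v = delta[i % nd], t0 = tau[i % nt];
    double lo = shift, hi = a - shift;
    double x = b * a;
    if (hi <= lo || x <= lo || x >= hi)
      stop("boundary separation too small for the requested step size");
    double vdt = v * dt;
    long steps = 0;
    for (;;) {
      x += vdt + sdt * rng.norm();
      ++steps;
      if (x >= hi) { up[i] = 1; break; }
      if (x <= lo) { up[i] = 0; break; }
      if (steps > 100000000L) stop("first-passage simulation did not terminate");
    }
    rt[i] = t0 + steps * dt;
  }
  return List::create(_["rt"] = rt, _["upper"] = up);
}
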