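#ifndef WIENERHDM_WFPT_H
#define WIENERHDM_WFPT_H

#include <cmath>
#include <algorithm>

// Shared Wiener first-passage density pieces (s = 1 throughout).
// wfpt_f0: standardised driftless lower-boundary density, small-time /
// large-time series with error-bounded truncation (`eps`); method 0 = pick
// the cheaper series, 1 = small-time, 2 = large-time.
inline double wfpt_f0(double tt, double w, double eps, int method) {
  if (tt <= 0.0) return 0.0;
  double ks;
  if (2.0 * std::sqrt(2.0 * M_PI * tt) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tt * std::log(2.0 * eps * std::sqrt(2.0 * M_PI * tt)));
    ks = std::max(ks, std::sqrt(tt) + 1.0);
  } else {
    ks = 2.0;
  }
  double kl;
  if (M_PI * tt * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tt * eps) / (M_PI * M_PI * tt));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tt));
  }
  bool small = (method == 1) || (method == 0 && ks < kl);
  double p = 0.0;
  if (small) {
    int K = (int)std::ceil(ks);
    int lo = -(K - 1) / 2;
    int hi = (int)std::ceil((K - 1) / 2.0);
    for (int k = lo; k <= hi; ++k) {
      double wk = w + 2.0 * k;
      p += wk * std::exp(-wk * wk / (2.0 * tt));
    }
    p /= std::sqrt(2.0 * M_PI * tt * tt * tt);
  } else {
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k)
      p += k * std::exp(-k * k * M_PI * M_PI * tt / 2.0) * std::sin(k * M_PI * w);
    p *= M_PI;
  }
  return p > 0.0 ? p : 0.0;
}

// Drift term of the density with drift marginalised over N(mu, eta^2),
// evaluated for the *lower* boundary at w = 0.5; the upper boundary is the
// reflection mu -> -mu (w is symmetric at 0.5). `b` = a * w.
inline double wfpt_marg_factor(double u, double m, double eta, double b) {
  double ex;
  double den = 1.0;
  if (eta <= 0.0) {
    ex = -m * b - m * m * u / 2.0;
  } else {
    double e2 = eta * eta;
    den = 1.0 + u * e2;
    ex = (e2 * b * b - 2.0 * b * m - m * m * u) / (2.0 * den);
  }
  // clamp: extreme drift proposals would otherwise overflow to Inf and
  // poison the log-likelihood (the matching series term underflows first)
  if (ex > 700.0) ex = 700.0;
  return std::exp(ex) / std::sqrt(den);
}

#endif
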