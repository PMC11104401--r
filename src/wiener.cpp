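// Wiener first-passage-time density, absorption probabilities and samplers.
//
// The density uses the small-time / large-time series representations with
// the term counts chosen per-call from the requested absolute tolerance
// (default 1e-9), switching to whichever series needs fewer terms.

#include <Rcpp.h>
using namespace Rcpp;

static const double WIENER_EPS = 1e-9;

// log density (normalized time tt = t / alpha^2, relative start w) of
// absorption at the LOWER boundary for a zero-drift process.
static double logf_std(double tt, double w) {
  if (tt <= 0.0) return R_NegInf;

  // number of terms required by each series for absolute error < eps
  double ks, kl;
  if (2.0 * WIENER_EPS * std::sqrt(2.0 * M_PI * tt) < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tt *
                         std::log(2.0 * WIENER_EPS * std::sqrt(2.0 * M_PI * tt)));
    ks = std::max(ks, std::sqrt(tt) + 1.0);
  } else {
    ks = 2.0;
  }
  if (M_PI * tt * WIENER_EPS < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tt * WIENER_EPS) / (M_PI * M_PI * tt));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tt));
  }

  double f;
  if (ks < kl) {            // small-time expansion
    int K = (int)std::ceil(ks);
    double s = 0.0;
    for (int k = -((K - 1) / 2); k <= K / 2; ++k) {
      double x = w + 2.0 * k;
      s += x * std::exp(-x * x / (2.0 * tt));
    }
    f = s / std::sqrt(2.0 * M_PI * tt * tt * tt);
  } else {                  // large-time expansion
    int K = (int)std::ceil(kl);
    double s = 0.0;
    for (int k = 1; k <= K; ++k) {
      s += k * std::exp(-k * k * M_PI * M_PI * tt / 2.0) * std::sin(k * M_PI * w);
    }
    f = s * M_PI;
  }
  if (f <= 0.0 || !R_FINITE(f)) return R_NegInf;
  return std::log(f);
}

// log density of a first passage at time t (decision time, tau already
// removed) at the LOWER boundary, for drift v, separation alpha, relative
// start w.
static double logf_lower(double t, double alpha, double w, double v) {
  if (t <= 0.0 || alpha <= 0.0 || w <= 0.0 || w >= 1.0) return R_NegInf;
  double tt = t / (alpha * alpha);
  return logf_std(tt, w) - 2.0 * std::log(alpha) - v * alpha * w -
         v * v * t / 2.0;
}

// signed-RT convention: rt > 0 means absorption at the UPPER boundary,
// rt < 0 at the lower boundary.  Upper-boundary density is the lower-boundary
// density under (v, w) -> (-v, 1 - w).
double wiener_logpdf_scalar(double rt, double alpha, double tau, double z,
                            double v) {
  double t = std::fabs(rt) - tau;
  if (!R_FINITE(rt) || t <= 0.0) return R_NegInf;
  if (rt > 0.0) return logf_lower(t, alpha, 1.0 - z, -v);
  return logf_lower(t, alpha, z, v);
}

//' @noRd
// [[Rcpp::export(name = ".wiener_logpdf_cpp")]]
NumericVector wiener_logpdf_cpp(NumericVector rt, NumericVector alpha,
                                NumericVector tau, NumericVector z,
                                NumericVector v) {
  int n = rt.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = wiener_logpdf_scalar(
        rt[i], alpha[alpha.size() > 1 ? i : 0], tau[tau.size() > 1 ? i : 0],
        z[z.size() > 1 ? i : 0], v[v.size() > 1 ? i : 0]);
  }
  return out;
}

// probability of absorption at the upper boundary; stable for large |v*a|
double wiener_upper_prob_scalar(double alpha, double z, double v) {
  double va = v * alpha;
  if (std::fabs(va) < 1e-10) return z;
  double num = -2.0 * va * z;    // exponent for numerator expm1
  double den = -2.0 * va;        // exponent for denominator expm1
  if (den > 700.0) {
    // strongly negative drift: P(upper) ~ exp(2 v a (1 - z))
    return std::exp(2.0 * va * (1.0 - z));
  }
  return std::expm1(num) / std::expm1(den);
}

//' @noRd
// [[Rcpp::export(name = ".wiener_upper_prob_cpp")]]
NumericVector wiener_upper_prob_cpp(NumericVector alpha, NumericVector z,
                                    NumericVector v) {
  int n = std::max(std::max(alpha.size(), z.size()), v.size());
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = wiener_upper_prob_scalar(alpha[alpha.size() > 1 ? i : 0],
                                      z[z.size() > 1 ? i : 0],
                                      v[v.size() > 1 ? i : 0]);
  }
  return out;
}

// Euler-Maruyama first-passage sampler.  Returns signed RTs (upper positive).
//' @noRd
// [[Rcpp::export(name = ".wiener_sample_euler_cpp")]]
NumericVector wiener_sample_euler_cpp(int n, NumericVector alpha,
                                      NumericVector tau, NumericVector z,
                                      NumericVector v, double dt,
                                      double t_max) {
  NumericVector out(n);
  double sdt = std::sqrt(dt);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    double a = alpha[alpha.size() > 1 ? i : 0];
    double t0 = tau[tau.size() > 1 ? i : 0];
    double x = z[z.size() > 1 ? i : 0] * a;
    double drift = v[v.size() > 1 ? i : 0];
    double t = 0.0;
    double rt = NA_REAL;
    while (t < t_max) {
      x += drift * dt + sdt * norm_rand();
      t += dt;
      if (x >= a) { rt = t0 + t; break; }
      if (x <= 0.0) { rt = -(t0 + t); break; }
    }
    out[i] = rt;
  }
  return out;
}
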