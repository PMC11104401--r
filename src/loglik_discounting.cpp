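// Pointwise log-likelihoods for the intertemporal-choice models.
//
// Parameter vector layouts (baselines then shifts, same order):
//   softmax : k_log, beta            | s_k, s_beta
//   ddm0    : alpha, tau, z, v       | s_alpha, s_tau, s_z, s_v
//   ddm_lin : k_log, alpha, tau, z, v_coeff          | shifts
//   ddm_s   : k_log, alpha, tau, z, v_coeff, v_max   | shifts
//
// Choices are coded 1 = larger-later (upper boundary), 0 = smaller-sooner.
// rt is the signed RT (LL positive); ignored by the softmax model.

#include <Rcpp.h>
using namespace Rcpp;

double wiener_logpdf_scalar(double rt, double alpha, double tau, double z,
                            double v);

static inline double sv_ll(double A, double D, double k_eff) {
  return A / (1.0 + std::exp(k_eff) * D);
}

static inline double sigmoid_drift(double m, double vmax) {
  return 2.0 * vmax / (1.0 + std::exp(-m)) - vmax;
}

// model: 0 softmax, 1 ddm0, 2 ddm_lin, 3 ddm_s
//' @noRd
// [[Rcpp::export(name = ".loglik_discounting_cpp")]]
NumericVector loglik_discounting_cpp(int model, NumericVector theta,
                                     NumericVector A, NumericVector D,
                                     IntegerVector I, IntegerVector choice,
                                     NumericVector rt) {
  int n = A.size();
  NumericVector out(n);
  int K = theta.size() / 2;

  for (int t = 0; t < n; ++t) {
    double ci = (double)I[t];
    double ll;
    if (model == 0) {
      double k_eff = theta[0] + theta[K + 0] * ci;
      double b_eff = theta[1] + theta[K + 1] * ci;
      double x = b_eff * (sv_ll(A[t], D[t], k_eff) - 20.0);
      // log P(LL) = log plogis(x); log P(SS) = log plogis(-x)
      ll = R::plogis(choice[t] == 1 ? x : -x, 0.0, 1.0, 1, 1);
    } else {
      double k_eff = 0.0, a_eff, tau_eff, z_eff, drift;
      if (model == 1) {
        a_eff   = theta[0] + theta[K + 0] * ci;
        tau_eff = theta[1] + theta[K + 1] * ci;
        z_eff   = theta[2] + theta[K + 2] * ci;
        drift   = theta[3] + theta[K + 3] * ci;
      } else {
        k_eff   = theta[0] + theta[K + 0] * ci;
        a_eff   = theta[1] + theta[K + 1] * ci;
        tau_eff = theta[2] + theta[K + 2] * ci;
        z_eff   = theta[3] + theta[K + 3] * ci;
        double vc_eff = theta[4] + theta[K + 4] * ci;
        double dsv = sv_ll(A[t], D[t], k_eff) - 20.0;
        drift = vc_eff * dsv;
        if (model == 3) {
          double vmax_eff = theta[5] + theta[K + 5] * ci;
          if (vmax_eff <= 0.0) { out[t] = R_NegInf; continue; }
          drift = sigmoid_drift(drift, vmax_eff);
        }
      }
      if (a_eff <= 0.0 || tau_eff < 0.0 || z_eff <= 0.0 || z_eff >= 1.0) {
        out[t] = R_NegInf; continue;
      }
      ll = wiener_logpdf_scalar(rt[t], a_eff, tau_eff, z_eff, drift);
    }
    out[t] = ll;
  }
  return out;
}
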