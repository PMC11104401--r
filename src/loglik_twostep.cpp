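// Pointwise log-likelihood for the two-step task models (sequential
// evaluation: choice terms first, then MF updates and decay of unchosen
// values; Q state and perseveration reset at session boundaries).
//
// Parameter vector layouts (baselines then shifts, same order):
//   softmax_hybrid (0): eta1, eta2, eta_decay, beta_mb, beta_mf, beta2, rho
//   rlddm_lin      (1): eta1, eta2, eta_decay, alpha_s1, alpha_s2, tau_s1,
//                       tau_s2, vcoeff_mf, vcoeff_mb, vcoeff_s2, rho
//   rlddm_s        (2): rlddm_lin layout + vmax_s1, vmax_s2
//   rlddm_null     (3): alpha_s1, alpha_s2, tau_s1, tau_s2, v_s1, v_s2
//
// Rewards must already be rescaled to [0, 1].  Signed RTs: the stimulus
// coded 2 maps to the upper boundary at each stage; z is fixed at 0.5.
// Excluded trials (include* = 0) contribute 0 to the likelihood but still
// drive learning.

#include <Rcpp.h>
using namespace Rcpp;

double wiener_logpdf_scalar(double rt, double alpha, double tau, double z,
                            double v);

static inline double sigmoid_drift(double m, double vmax) {
  return 2.0 * vmax / (1.0 + std::exp(-m)) - vmax;
}

//' @noRd
// [[Rcpp::export(name = ".loglik_twostep_cpp")]]
NumericVector loglik_twostep_cpp(int model, NumericVector theta,
                                 IntegerVector s1, IntegerVector s2state,
                                 IntegerVector a2, NumericVector r,
                                 IntegerVector I, NumericVector rt1,
                                 NumericVector rt2, IntegerVector include1,
                                 IntegerVector include2,
                                 IntegerVector session, double p_common) {
  int n = s1.size();
  NumericVector out(n);
  int K = theta.size() / 2;
  bool learns = (model != 3);

  double q1[2], q2[2][2];
  int prev = 0;          // previous S1 action, 0 = none
  int cur_session = INT_MIN;

  for (int t = 0; t < n; ++t) {
    if (session[t] != cur_session) {
      cur_session = session[t];
      q1[0] = q1[1] = 0.5;
      q2[0][0] = q2[0][1] = q2[1][0] = q2[1][1] = 0.5;
      prev = 0;
    }
    double ci = (double)I[t];
    double ll = 0.0;
    int c1 = s1[t] - 1, st = s2state[t] - 1, c2 = a2[t] - 1;

    // model-based values from the current MF stage-2 table
    double m0 = std::max(q2[0][0], q2[0][1]);
    double m1 = std::max(q2[1][0], q2[1][1]);
    double qmb[2] = { p_common * m0 + (1.0 - p_common) * m1,
                      p_common * m1 + (1.0 - p_common) * m0 };

    double eta1_eff = 0, eta2_eff = 0, dec_eff = 0;
    if (learns) {
      eta1_eff = theta[0] + theta[K + 0] * ci;
      eta2_eff = theta[1] + theta[K + 1] * ci;
      dec_eff  = theta[2] + theta[K + 2] * ci;
      if (eta1_eff < 0.0 || eta1_eff > 1.0 || eta2_eff < 0.0 ||
          eta2_eff > 1.0 || dec_eff < 0.0 || dec_eff > 1.0) {
        std::fill(out.begin(), out.end(), R_NegInf);
        return out;
      }
    }

    if (model == 0) {
      double bmb = theta[3] + theta[K + 3] * ci;
      double bmf = theta[4] + theta[K + 4] * ci;
      double b2  = theta[5] + theta[K + 5] * ci;
      double rho = theta[6] + theta[K + 6] * ci;
      // stage 1: softmax over MB + MF values with perseveration bonus
      double u0 = bmb * qmb[0] + bmf * q1[0] + (prev == 1 ? rho : 0.0);
      double u1 = bmb * qmb[1] + bmf * q1[1] + (prev == 2 ? rho : 0.0);
      double uc = (c1 == 0 ? u0 : u1);
      double um = std::max(u0, u1);
      ll += uc - (um + std::log(std::exp(u0 - um) + std::exp(u1 - um)));
      // stage 2: softmax over the visited state's MF values
      double d2 = b2 * (q2[st][c2] - q2[st][1 - c2]);
      ll += R::plogis(d2, 0.0, 1.0, 1, 1);
    } else {
      int off = learns ? 3 : 0;
      double a_s1   = theta[off + 0] + theta[K + off + 0] * ci;
      double a_s2   = theta[off + 1] + theta[K + off + 1] * ci;
      double tau_s1 = theta[off + 2] + theta[K + off + 2] * ci;
      double tau_s2 = theta[off + 3] + theta[K + off + 3] * ci;
      if (a_s1 <= 0.0 || a_s2 <= 0.0 || tau_s1 < 0.0 || tau_s2 < 0.0) {
        std::fill(out.begin(), out.end(), R_NegInf);
        return out;
      }
      double v1, v2;
      if (model == 3) {
        v1 = theta[4] + theta[K + 4] * ci;
        v2 = theta[5] + theta[K + 5] * ci;
      } else {
        double vmf = theta[7] + theta[K + 7] * ci;
        double vmb = theta[8] + theta[K + 8] * ci;
        double vs2 = theta[9] + theta[K + 9] * ci;
        double rho = theta[10] + theta[K + 10] * ci;
        double rep = (prev == 2 ? 1.0 : (prev == 1 ? -1.0 : 0.0));
        v1 = vmb * (qmb[1] - qmb[0]) + vmf * (q1[1] - q1[0]) + rho * rep;
        v2 = vs2 * (q2[st][1] - q2[st][0]);
        if (model == 2) {
          double vm1 = theta[11] + theta[K + 11] * ci;
          double vm2 = theta[12] + theta[K + 12] * ci;
          if (vm1 <= 0.0 || vm2 <= 0.0) {
            std::fill(out.begin(), out.end(), R_NegInf);
            return out;
          }
          v1 = sigmoid_drift(v1, vm1);
          v2 = sigmoid_drift(v2, vm2);
        }
      }
      if (include1[t])
        ll += wiener_logpdf_scalar(rt1[t], a_s1, tau_s1, 0.5, v1);
      if (include2[t])
        ll += wiener_logpdf_scalar(rt2[t], a_s2, tau_s2, 0.5, v2);
    }
    out[t] = ll;

    if (learns) {
      // MF updates: stage-2 prediction error feeds both stages; the
      // stage-1 error uses the pre-update stage-2 value
      double d2 = r[t] - q2[st][c2];
      double d1 = q2[st][c2] - q1[c1];
      q2[st][c2] += eta2_eff * d2;
      q1[c1] += eta1_eff * d1 + eta2_eff * d2;
      // decay all unchosen values toward the walk mean 0.5
      q1[1 - c1] = q1[1 - c1] * dec_eff + (1.0 - dec_eff) * 0.5;
      for (int s = 0; s < 2; ++s)
        for (int a = 0; a < 2; ++a)
          if (!(s == st && a == c2))
            q2[s][a] = q2[s][a] * dec_eff + (1.0 - dec_eff) * 0.5;
    }
    prev = s1[t];
  }
  return out;
}
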