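// Generative rollout of the two-step task for one subject: transition
// sampling, choice generation (softmax probabilities or Euler-discretized
// Wiener first passages), reward delivery from the supplied walk rows, and
// the same MF/MB updating + decay as the likelihood.
//
// walks: n x 4 matrix of rescaled rewards, columns (state1,a1), (state1,a2),
// (state2,a1), (state2,a2), already aligned with the trial sequence.

#include <Rcpp.h>
using namespace Rcpp;

static inline double sigmoid_drift(double m, double vmax) {
  return 2.0 * vmax / (1.0 + std::exp(-m)) - vmax;
}

// Euler first passage with z = 0.5; signed rt (upper positive)
static double euler_fp(double alpha, double tau, double z, double v,
                       double dt, double t_max) {
  double x = z * alpha, t = 0.0, sdt = std::sqrt(dt);
  while (t < t_max) {
    x += v * dt + sdt * norm_rand();
    t += dt;
    if (x >= alpha) return tau + t;
    if (x <= 0.0) return -(tau + t);
  }
  return NA_REAL;
}

//' @noRd
// [[Rcpp::export(name = ".simulate_twostep_subject_cpp")]]
List simulate_twostep_subject_cpp(int model, NumericVector theta,
                                  NumericMatrix walks, IntegerVector I,
                                  IntegerVector session, double p_common,
                                  double dt, double t_max) {
  int n = walks.nrow();
  int K = theta.size() / 2;
  bool learns = (model != 3), ddm = (model != 0);
  IntegerVector s1(n), trans(n), s2state(n), a2(n);
  NumericVector r(n), rt1(n, NA_REAL), rt2(n, NA_REAL);
  RNGScope scope;

  double q1[2], q2[2][2];
  int prev = 0;
  int cur_session = INT_MIN;

  for (int t = 0; t < n; ++t) {
    if (session[t] != cur_session) {
      cur_session = session[t];
      q1[0] = q1[1] = 0.5;
      q2[0][0] = q2[0][1] = q2[1][0] = q2[1][1] = 0.5;
      prev = 0;
    }
    double ci = (double)I[t];
    double m0 = std::max(q2[0][0], q2[0][1]);
    double m1 = std::max(q2[1][0], q2[1][1]);
    double qmb[2] = { p_common * m0 + (1.0 - p_common) * m1,
                      p_common * m1 + (1.0 - p_common) * m0 };

    int c1, c2, st;
    if (model == 0) {
      double bmb = theta[3] + theta[K + 3] * ci;
      double bmf = theta[4] + theta[K + 4] * ci;
      double b2  = theta[5] + theta[K + 5] * ci;
      double rho = theta[6] + theta[K + 6] * ci;
      double u0 = bmb * qmb[0] + bmf * q1[0] + (prev == 1 ? rho : 0.0);
      double u1 = bmb * qmb[1] + bmf * q1[1] + (prev == 2 ? rho : 0.0);
      double p1 = 1.0 / (1.0 + std::exp(u0 - u1));
      c1 = (unif_rand() < p1) ? 1 : 0;
      // transition
      bool common = unif_rand() < p_common;
      st = common ? c1 : 1 - c1;
      double p2 = 1.0 / (1.0 + std::exp(b2 * (q2[st][0] - q2[st][1])));
      c2 = (unif_rand() < p2) ? 1 : 0;
      trans[t] = common ? 1 : 0;
    } else {
      int off = learns ? 3 : 0;
      double a_s1   = theta[off + 0] + theta[K + off + 0] * ci;
      double a_s2   = theta[off + 1] + theta[K + off + 1] * ci;
      double tau_s1 = theta[off + 2] + theta[K + off + 2] * ci;
      double tau_s2 = theta[off + 3] + theta[K + off + 3] * ci;
      double v1, v2base = 0.0;
      if (model == 3) {
        v1 = theta[4] + theta[K + 4] * ci;
        v2base = theta[5] + theta[K + 5] * ci;
      } else {
        double vmf = theta[7] + theta[K + 7] * ci;
        double vmb = theta[8] + theta[K + 8] * ci;
        double rho = theta[10] + theta[K + 10] * ci;
        double rep = (prev == 2 ? 1.0 : (prev == 1 ? -1.0 : 0.0));
        v1 = vmb * (qmb[1] - qmb[0]) + vmf * (q1[1] - q1[0]) + rho * rep;
        if (model == 2)
          v1 = sigmoid_drift(v1, theta[11] + theta[K + 11] * ci);
      }
      double srt1 = euler_fp(a_s1, tau_s1, 0.5, v1, dt, t_max);
      c1 = (srt1 > 0) ? 1 : 0;
      rt1[t] = std::fabs(srt1);
      bool common = unif_rand() < p_common;
      st = common ? c1 : 1 - c1;
      trans[t] = common ? 1 : 0;
      double v2;
      if (model == 3) {
        v2 = v2base;
      } else {
        double vs2 = theta[9] + theta[K + 9] * ci;
        v2 = vs2 * (q2[st][1] - q2[st][0]);
        if (model == 2)
          v2 = sigmoid_drift(v2, theta[12] + theta[K + 12] * ci);
      }
      double srt2 = euler_fp(a_s2, tau_s2, 0.5, v2, dt, t_max);
      c2 = (srt2 > 0) ? 1 : 0;
      rt2[t] = std::fabs(srt2);
    }

    double rew = walks(t, 2 * st + c2);
    s1[t] = c1 + 1; s2state[t] = st + 1; a2[t] = c2 + 1; r[t] = rew;

    if (learns) {
      double eta1_eff = theta[0] + theta[K + 0] * ci;
      double eta2_eff = theta[1] + theta[K + 1] * ci;
      double dec_eff  = theta[2] + theta[K + 2] * ci;
      double d2 = rew - q2[st][c2];
      double d1 = q2[st][c2] - q1[c1];
      q2[st][c2] += eta2_eff * d2;
      q1[c1] += eta1_eff * d1 + eta2_eff * d2;
      q1[1 - c1] = q1[1 - c1] * dec_eff + (1.0 - dec_eff) * 0.5;
      for (int s = 0; s < 2; ++s)
        for (int a = 0; a < 2; ++a)
          if (!(s == st && a == c2))
            q2[s][a] = q2[s][a] * dec_eff + (1.0 - dec_eff) * 0.5;
    }
    prev = c1 + 1;
  }
  return List::create(_["s1"] = s1, _["transition"] = trans,
                      _["s2_state"] = s2state, _["s2_action"] = a2,
                      _["reward"] = r, _["rt_s1"] = rt1, _["rt_s2"] = rt2);
}
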