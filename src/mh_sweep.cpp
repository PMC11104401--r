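// One component-wise random-walk Metropolis sweep over a subject's
// parameter vector, conditional on the group-level means and SDs.
// Keeping the sweep in C++ avoids per-proposal R dispatch; the sampler
// loop proper lives in R (fit_hierarchical).

#include <Rcpp.h>
using namespace Rcpp;

NumericVector loglik_discounting_cpp(int model, NumericVector theta,
                                     NumericVector A, NumericVector D,
                                     IntegerVector I, IntegerVector choice,
                                     NumericVector rt);
NumericVector loglik_twostep_cpp(int model, NumericVector theta,
                                 IntegerVector s1, IntegerVector s2state,
                                 IntegerVector a2, NumericVector r,
                                 IntegerVector I, NumericVector rt1,
                                 NumericVector rt2, IntegerVector include1,
                                 IntegerVector include2,
                                 IntegerVector session, double p_common);

static double ll_sum(NumericVector x) {
  double s = 0.0;
  for (int i = 0; i < x.size(); ++i) {
    if (x[i] == R_NegInf) return R_NegInf;
    s += x[i];
  }
  return s;
}

// task: 0 = discounting, 1 = twostep.  data is the per-subject list built
// by the R sampler (fields in fixed order, see .subject_data()).
static double subject_ll(int task, int model, NumericVector theta,
                         List data) {
  if (task == 0) {
    return ll_sum(loglik_discounting_cpp(model, theta, data["A"], data["D"],
                                         data["I"], data["choice"],
                                         data["rt"]));
  }
  return ll_sum(loglik_twostep_cpp(
      model, theta, data["s1"], data["s2state"], data["a2"], data["r"],
      data["I"], data["rt1"], data["rt2"], data["include1"],
      data["include2"], data["session"], as<double>(data["p_common"])));
}

//' @noRd
// [[Rcpp::export(name = ".mh_sweep_cpp")]]
List mh_sweep_cpp(int task, int model, NumericVector theta_in, List data,
                  NumericVector mu, NumericVector sigma,
                  NumericVector prop_sd, double cur_ll) {
  NumericVector theta = clone(theta_in);
  int J = theta.size();
  IntegerVector acc(J);
  RNGScope scope;

  if (!R_FINITE(cur_ll)) cur_ll = subject_ll(task, model, theta, data);

  for (int j = 0; j < J; ++j) {
    double old = theta[j];
    double prop = old + prop_sd[j] * norm_rand();
    theta[j] = prop;
    double new_ll = subject_ll(task, model, theta, data);
    double lr = new_ll - cur_ll +
                R::dnorm(prop, mu[j], sigma[j], 1) -
                R::dnorm(old, mu[j], sigma[j], 1);
    if (R_FINITE(new_ll) && std::log(unif_rand()) < lr) {
      cur_ll = new_ll;
      acc[j] = 1;
    } else {
      theta[j] = old;
    }
  }

  // anti-correlated (baseline, shift) pair moves: baseline + d, shift - d
  // leaves the gambling-context effective value unchanged, traversing the
  // posterior ridge that couples the two parameters
  int K = J / 2;
  for (int j = 0; j < K; ++j) {
    double d = prop_sd[j] * norm_rand();
    double ob = theta[j], os = theta[K + j];
    theta[j] = ob + d;
    theta[K + j] = os - d;
    double new_ll = subject_ll(task, model, theta, data);
    double lr = new_ll - cur_ll +
                R::dnorm(theta[j], mu[j], sigma[j], 1) -
                R::dnorm(ob, mu[j], sigma[j], 1) +
                R::dnorm(theta[K + j], mu[K + j], sigma[K + j], 1) -
                R::dnorm(os, mu[K + j], sigma[K + j], 1);
    if (R_FINITE(new_ll) && std::log(unif_rand()) < lr) {
      cur_ll = new_ll;
    } else {
      theta[j] = ob;
      theta[K + j] = os;
    }
  }
  return List::create(_["theta"] = theta, _["ll"] = cur_ll, _["acc"] = acc);
}
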