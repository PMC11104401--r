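# ctxshift

Hierarchical Bayesian modelling of **context effects** on two
computational markers of addiction: **temporal discounting** and
**model-based vs. model-free control** in sequential reinforcement
learning.  The package is built for the paradigm in which regular
gamblers perform an intertemporal-choice task and a two-step task twice —
once in a neutral environment and once in a gambling-related one — and
every model parameter `x` carries an additive *context-shift* parameter
`s_x`, active on gambling-context trials (`I_t = 1`):

```
x_eff(t) = x + s_x * I_t
```

so that "discounting steepens in the gambling context" is a posterior
statement about the group-level mean of `s_k`.

## Models

**Intertemporal choice** — hyperbolic discounting in log-space,

```
SV(LL_t) = A_t / (1 + exp(k + s_k * I_t) * D_t),      SV(SS) = 20 €
```

with four choice rules: `softmax` (choices only), and three drift
diffusion models over signed RTs (larger-later = upper boundary):
`ddm0` (value-free drift), `ddm_lin` (drift proportional to
`SV(LL) - 20`) and `ddm_s` (the linear drift passed through an odd
sigmoid with asymptote `v_max`).

**Two-step task** — a hybrid learner with separate stage learning rates,
decay of unchosen values toward the reward-walk mean, perseveration, and
Bellman model-based values over the 70/30 transition structure; choice
rules `softmax_hybrid`, `rlddm_lin`, `rlddm_s` (per-stage Wiener
likelihoods, `z = 0.5`) and the RT-null `rlddm_null`.

Estimation is Metropolis-within-Gibbs with compiled (Rcpp) likelihoods,
uniform baseline priors over plausible ranges, zero-centered Gaussian
shift priors, Gamma priors on group precisions, a rank-normalized split
R-hat gate at 1.02, WAIC model comparison, directional Bayes factors by
kernel density estimation, and posterior predictive checks on
RT-by-conflict bins, stage-2 reward-difference bins, choice accuracy and
stay probabilities.  Everything is exercisable end-to-end on synthetic
cohorts; deposited raw data can be read through `read_choice_data()`
with a user-supplied `schema_map`.

## Worked example

Simulate a 12-gambler cohort on the discounting task (two
counterbalanced 140-trial sessions each, neutral and gambling context)
and ask whether the discount rate shifts:

```r
library(ctxshift)

spec   <- cohort_spec(n_subjects = 12, model = "softmax", seed = 7)
trials <- simulate_discounting_cohort(spec)
fit    <- fit_hierarchical("softmax", trials,
                           mcmc = mcmc_control(chains = 2, burnin = 600,
                                               iter = 1200), seed = 7)
print(fit)
summary(fit)
```

```
Hierarchical context-shift fit: model 'softmax' (discounting task)
  12 subjects, 3360 trials, 2 chains x 1200 retained draws
  max R-hat 1.006 (gate 1.02) - converged
  group-level posterior means:
 k_log   beta    s_k s_beta
-3.173  0.150  0.997  0.014

  parameter   mean    sd hdi95_low hdi95_high  rhat directional_bf evidence
1     k_log -3.173 0.335    -3.876     -2.538 1.000             NA     <NA>
2      beta  0.150 0.021     0.109      0.192 1.000             NA     <NA>
3       s_k  0.997 0.128     0.732      1.244 1.000            Inf  extreme
4    s_beta  0.014 0.018    -0.022      0.050 1.004          3.893 moderate
```

Read: the cohort's baseline log discount rate is about −3.2; the
gambling context raises it by ≈1.0 (this synthetic cohort was generated
with a positive shift), with every posterior draw above zero ("extreme"
directional evidence), while choice stochasticity `beta` barely moves.
The same interface fits the DDM variants (after
`preprocess_discounting_rts()`, which signs and trims RTs) and the
two-step models; `compare_models()` ranks fits by WAIC,
`ppc_discounting()` / `ppc_twostep()` run the predictive checks, and
`run_pipeline()` drives simulate → preprocess → fit → compare → PPC from
a single config with a JSON manifest.

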