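---
title: "Context-shift models of discounting and two-step learning: methods"
author: "ctxshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-shift models of discounting and two-step learning: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctxshift)
```

## The scientific problem

Temporal discounting (the devaluation of delayed rewards) and the balance
of model-based (MB) versus model-free (MF) control in sequential
decision-making are two candidate trans-diagnostic markers of addiction.
Both are measurable with standard laboratory tasks — an intertemporal
choice task and the two-step sequential task — and both may be modulated
by the *environment* in which testing happens (for instance a gambling
venue versus a neutral café, for regular slot-machine gamblers).

`ctxshift` models that environmental modulation directly.  Every model
parameter $x$ is accompanied by an additive *context-shift* parameter
$s_x$ that is active when the trial's dummy-coded context indicator
$I_t = 1$:

$$x_{\mathrm{eff}}(t) = x + s_x \cdot I_t .$$

Baseline parameters and shifts each get their own group-level
distribution, so a cohort-level statement like "discounting is steeper in
the gambling context" becomes a posterior statement about the group mean
of $s_k$.

## Models

### Intertemporal choice

Subjective value of the delayed (larger-later, LL) option follows
single-parameter hyperbolic discounting with the discount rate in
log-space:

$$SV(LL_t) = \frac{A_t}{1 + \exp(k + s_k I_t)\, D_t},$$

with $A_t$ the LL amount (a multiple of the fixed 20€ immediate reward)
and $D_t$ the delay in days.  Four choice rules map values onto behavior:

* **softmax** — logistic choice in
  $(\beta + s_\beta I_t)(SV(LL_t) - 20)$; choices only.
* **ddm0** — a drift diffusion model with context-shifted boundary
  separation $\alpha$, non-decision time $\tau$, starting point $z$ and a
  *value-independent* drift $v$; the joint choice/RT likelihood is the
  Wiener first-passage-time density, with the upper boundary mapped to LL
  choices and smaller-sooner RTs entering with negative sign.
* **ddm_lin** — trial-wise drift
  $v_t = (v_{\mathrm{coeff}} + s_{v_{\mathrm{coeff}}} I_t)(SV(LL_t)-20)$.
* **ddm_s** — the same drift input passed through an odd sigmoid with
  asymptote $v_{\max} + s_{v_{\max}} I_t$:
  $S(m) = \frac{2 v_{\max}}{1 + e^{-m}} - v_{\max}$, capturing saturating
  value sensitivity of RTs.

### Two-step task

A modified hybrid MF/MB learner: separate stage-1/stage-2 learning rates
$\eta_1, \eta_2$, an eligibility trace fixed at 1, and decay of every
*unchosen* option value toward the reward-walk mean (0.5 after rescaling
rewards from 0–100 points to $[0,1]$) with retention rate
$\eta_{\mathrm{decay}}$:

$$Q \leftarrow Q\,\eta_{\mathrm{decay},s} + (1-\eta_{\mathrm{decay},s})\,0.5 .$$

Stage-2 prediction errors update the chosen stage-2 value and, jointly
with the stage-1 error (computed against the *pre-update* stage-2 value),
the chosen stage-1 value.  MB values are the transition-weighted Bellman
lookahead over the stage-2 maxima (70/30 structure).  Choice rules:

* **softmax_hybrid** — stage-1 softmax over
  $\beta_{MB} Q_{MB} + \beta_{MF} Q_{MF,S1} + \rho\,\mathrm{rep}(a)$
  (perseveration bonus $\rho$ for repeating the previous stage-1 choice)
  and stage-2 softmax with weight $\beta_2$.
* **rlddm_lin / rlddm_s** — drift diffusion per stage with $z = 0.5$ and
  stage-specific $\alpha, \tau$; the stage-1 drift is
  $v_{S1} = v_{MB}\Delta Q_{MB} + v_{MF}\Delta Q_{MF} + \rho\,\mathrm{rep}$,
  the stage-2 drift $v_{S2}\Delta Q_{S2}$, optionally sigmoid-squashed
  with stage-specific asymptotes.  The stimulus coded 2 maps to the upper
  boundary; $\mathrm{rep}$ is $\pm 1$ by the previous choice's boundary.
* **rlddm_null** — per-stage DDM without value modulation, the RT-level
  null model.

A caveat worth documenting: with separate learning rates the stage-1
update $Q_1 \mathrel{+}= \eta_1 \delta_1 + \eta_2 \delta_2$ is a convex
combination of $Q_1$, $Q_2$ and $r$ only when $\eta_1 \ge \eta_2$; when
$\eta_2 > \eta_1$, stage-1 values can transiently leave $[0,1]$.  We
implement the update faithfully (no clipping); the boundedness property
test asserts the regime in which boundedness is provable.

## Wiener first-passage likelihood

The signed-RT density switches between the small-time and large-time
series expansions, picking whichever needs fewer terms for an absolute
truncation tolerance of $10^{-9}$.  Sampling offers two routes: an
inverse-CDF method (boundary from the closed-form absorption probability,
passage time by numerical inversion of the series CDF on a 4096-point
grid — effectively exact, used for large draw counts) and Euler–Maruyama
path simulation (default step $10^{-3}$–$10^{-4}$ s; bias shrinks as
$\sqrt{dt}$), used inside the generative rollouts where per-trial drifts
change constantly.

## Hierarchical estimation

Subject-level parameter vectors are exchangeable Gaussian draws per
parameter: $\theta_{s,j} \sim \mathcal N(\mu_j, \sigma_j^2)$.  Priors:
uniform on each baseline group mean over a plausible range (declared in
`ctx_priors()`, e.g. $\log k \in [-8, 1]$, rates in $[0,1]$, boundary
separations in $[0.05, 5]$, non-decision times in $[0.05, 2]$ seconds),
zero-centered Gaussians on shift means (SD 0.5 for rate/probability/time
scales, 2–5 otherwise), and Gamma(0.001, 0.001) on group precisions.
These ranges are package defaults — results-critical comparisons should
check sensitivity to them.

The sampler is Metropolis-within-Gibbs: compiled component-wise
random-walk Metropolis sweeps over each subject's parameters (proposal
scales adapted toward 44% acceptance during burn-in), plus
anti-correlated (baseline $+d$, shift $-d$) pair moves that traverse the
ridge created by contexts informing baseline vs. baseline + shift; group
means and precisions then update by conjugate (or truncated-normal)
Gibbs steps.  Support violations (effective rates outside $[0,1]$,
non-positive boundaries, $|RT| \le \tau$) reject proposals through the
likelihood.

Convergence is gated on rank-normalized split R-hat $\le 1.02$ for all
group-level and subject-level parameters, with automatic sampling
extensions; a fit that still fails the gate is *flagged* and returned
rather than discarded, mirroring how occasional hold-outs are reported
in practice.  Pointwise log-likelihoods are stored at a spread of
retained draws for WAIC ($-2(\mathrm{lppd} - p_{\mathrm{WAIC}})$, lower
is better); model comparisons refuse to run across non-identical trial
sets (data fingerprints).

Directional Bayes factors for shift parameters are the ratio of
kernel-density-estimated posterior mass above vs. below zero (Gaussian
kernel, default bandwidth, grid spanning the draws ±3 bandwidths), read
on the usual evidence bands (1–3 anecdotal, >3 moderate, >10 strong,
>30 very strong, >100 extreme, reciprocals for the opposite direction).

The covariate extension replaces the group mean of one shift (by default
$s_k$) with a linear combination of standardized per-subject
questionnaire scores; slopes get conjugate Gaussian updates and are
reported with their directional BFs.

## Synthetic cohorts: the study conditions

The generator reproduces the task designs: 16 LL multipliers × 6 delays
per counterbalanced version (both multiplier sets average
$32.405/16 \approx 2.025$; the 140-trial sessions are reached by uniform
resampling of the 96-cell cross, since no larger printed option set
exists — the generator logs this), 20€ fixed SS, randomized screen
side; and for the two-step task 300-trial sessions, four Gaussian reward
walks (SD 2.5 points, reflected at 0 and 100; the second version is the
first reversed) and the 70/30 transition structure.  Each simulated
subject completes one session per context in counterbalanced order.

Default group-level generating distributions are the package's study
conditions: baseline means are mid-range values plausible for regular
gamblers (e.g. $\log k = -3.5 \pm 0.8$, softmax $\beta = 0.15$ €$^{-1}$,
$\alpha \approx 1.6$–$2.2$, $\tau \approx 0.3$–$0.35$ s, learning rates
0.35–0.45), and shift means follow the fitted context effects reported
for each model class (discount-rate shift 0.77 under softmax and 0.40
under the sigmoid DDM, $s_{v_{\max}} = 0.33$; learning-rate shift 0.40,
MF-weight shift $-1.14$, MB-weight shift $+1.08$ for the hybrid model,
and the corresponding drift-coefficient shifts for the RLDDM).  These
were chosen once, so that simulated cohorts embody the effects the
models exist to detect.

What the generator does *not* emulate: attention lapses and contaminant
RTs, within-session non-stationarity of DDM parameters, side biases, or
any mismatch between the assumed and true generative family.  Passing
recovery tests therefore demonstrates internal consistency of the
estimation machinery, not robustness to real-data misspecification.

## Numerical and design choices

* **RT preprocessing.** Smaller-sooner RTs are negated; per participant
  the fastest and slowest 2.5% of trials are trimmed (per-tail counts
  rounded down, ties by trial order); two-step RTs below 150 ms are
  excluded per stage.  Excluded two-step trials still drive learning —
  they only leave the likelihood.
* **Stage-1 prediction-error timing.** $\delta_1$ uses the pre-update
  stage-2 value (the standard hybrid convention); update order is
  stage-2 value, then stage-1, then decay of all unchosen entries.
* **Boundary assignment.** Stimulus 2 is the upper boundary at both
  stages; recorded so that drift signs are interpretable.
* **Trimming and binning.** Posterior predictive conflict bins are
  per-subject, per-context equal-count quintiles of $|SV(LL) - 20|$
  computed at the subject's median posterior $\log k$; binning refuses
  degenerate (fewer than five distinct conflict values) cells.
* **Accuracy.** "Predicted choice" means model probability > 0.5, ties
  counted as one half.
* **Sampler scale.** Default settings (2 chains, 1000 burn-in, 2000
  iterations, thinning 2) suit cohorts of 10–30 subjects; the test suite
  and the acceptance script run reduced configurations (documented in
  each call) chosen so a full check runs on a single CPU in minutes.
  Subject-level identifiability at these reduced scales differs by
  parameter: discount rates, boundary separations, non-decision times
  and perseveration recover well, whereas the MB/MF softmax weights and
  the sigmoid drift parameters trade off against each other and recover
  reliably only at the group level.  Recovery tests therefore assess
  subject-level correlation on a designated strongly identified
  parameter per family (the acceptance suite asserts $r > 0.7$ there).
* **Model comparison scope.** WAIC is only comparable across models of
  the same observation space.  Choices-only (softmax) and choice+RT
  (DDM) likelihoods live on different spaces, so recovery confusion
  matrices are computed within the DDM family for each task.

## Known limitations

* The sampler is a general-purpose Metropolis-within-Gibbs scheme; for
  the richest model (26-parameter sigmoid RLDDM) convergence at the 1.02
  gate needs thousands of iterations, and short smoke fits are flagged
  non-converged by design.
* Group-level uniform priors use package-default ranges; the original
  analyses defer exact ranges to their code repository, so quantitative
  agreement of posterior *means* is expected only to cohort-level
  precision.
* The two-step posterior predictive replay reconstructs unvisited-state
  rewards from the visited pair, which is adequate for RT/choice pattern
  checks but not for exact walk replay.
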