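Package: ctxshift
Title: Context-Shift Models of Temporal Discounting and Two-Step
    Reinforcement Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical Bayesian modelling of environment (context) effects
    on intertemporal choice and sequential reinforcement learning. Implements
    hyperbolic temporal discounting with softmax and drift-diffusion choice
    rules (null, linear and sigmoid drift-rate scaling), a modified hybrid
    model-free/model-based learner for the two-step task with per-stage
    learning rates, decay of unchosen values and perseveration, and
    drift-diffusion variants thereof.  Every model parameter carries an
    additive context-shift parameter estimated with its own group-level
    distribution.  Includes task simulators (reward random walks, 70/30
    transition structure, counterbalanced designs), an adaptive
    Metropolis-within-Gibbs sampler with rank-normalized split R-hat
    convergence gating, WAIC model comparison, directional Bayes factors via
    kernel density estimation, posterior predictive checks on choices and
    response times, and model-agnostic mixed-model analyses.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    lme4
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
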