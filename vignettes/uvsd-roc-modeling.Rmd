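---
title: "Unequal-variance signal detection modeling of confidence-rating ROCs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unequal-variance signal detection modeling of confidence-rating ROCs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdtroc)
```

## The model

A recognition probe elicits a latent memory strength: `N(mu_target,
sigma_target)` if the probe was studied, `N(mu_lure, sigma_lure)` if not.
Five strictly ascending criteria `c1 < ... < c5` partition the strength
axis into six confidence categories ordered "definitely old" to
"definitely new"; a strength above `c5` produces "definitely old", one
below `c1` "definitely new". The probability of category `k` is the
Gaussian mass between the adjacent criteria, so observed rating counts for
one participant cell are multinomial, and the log-likelihood is

```
sum_k n_target_k log p_target_k + sum_k n_lure_k log p_lure_k
```

with the constant multinomial coefficient omitted. Two identification
conventions are supported as first-class parameterizations: the lure mean
is always fixed at 0, and either the target SD is fixed at 1
(`fix_target_sd`, the usual choice for study-test designs, so the free
`sigma_lure` *is* the lure-to-target SD ratio) or the lure distribution is
fixed at `N(0, 1)` (`fix_lure_sd`, the convention for the serial-position
model). The z-transformed ROC implied by the model is exactly the line
`z(HR) = mu_target / sigma_target + (sigma_lure / sigma_target) z(FAR)`,
which is what `population_zroc()` returns and what the least-squares
`zroc_fit()` estimates from data.

Four variants differ only in the admissible set of the SD ratio: `EV`
(ratio fixed at 1), `UV_free` (ratio positive and free),
`UV_target_greater` (ratio in (0, 1), i.e. targets more variable), and
`UV_lure_greater` (ratio above 1). The serial-position variant lets
`mu_target` and `sigma_target` differ by study position while sharing the
five criteria and the standard-normal lure distribution across positions;
with all positions equal it collapses exactly to the basic model
(`serial_log_likelihood()` is tested against that identity).

## Empirical zROC estimation

`cumulative_rates()` cumulates counts from the "definitely old" end and
drops the trivial (1, 1) endpoint. `zroc_fit()` drops points whose hit or
false-alarm rate is exactly 0 or 1 rather than applying a continuity
correction: no correction is assumed by the model, and treating one-point
zROCs as missing mirrors how degenerate cells are handled downstream
(vertical zROCs — fewer than two distinct false-alarm rates, detected with
an absolute tolerance of 1e-12 on the rate scale — return `valid = FALSE`
instead of an arbitrary slope). These cells occur in real short-list data
when high-performing participants use only the extreme keys, so they are
reported as missing values, never errors.

## The hierarchy and its priors

Each participant contributes a transformed parameter vector per condition:
the target mean(s) (identity scale), a free-SD term mapped onto the
variant's admissible region (`exp` for `UV_free`, logistic onto (0, 1) or
shifted exponential onto (1, Inf) for the constrained variants — so
DE-MCMC proposals need no rejection and constrained fits can never emit an
inadmissible draw), the first criterion, and four log-spacings between
adjacent criteria (ascending order by construction). Participant vectors
are exchangeable normal draws around group locations with group scales;
conditions share nothing.

Priors are minimally informative and overridable from `prior =`: group
locations `N(0, 3)` for means and the criterion anchor, `N(0, 1)` for
log-SD and log-spacing terms; group scales half-normal(0, 1), with
non-positive proposed scales treated as zero-density states rather than
errors. These are this package's own defaults, chosen so the prior is flat
relative to the likelihood at realistic trial counts; sensitivity to them
is easiest to probe through `run_recovery()`.

## Sampling

`fit_sdt()` samples the joint posterior with differential-evolution MCMC:
every chain holds the full parameter vector, and each iteration updates,
per block, along `gamma (theta_m - theta_n)` plus Uniform(-0.001, 0.001)
jitter, accepted by the Metropolis rule. Blocks are (a) each participant's
vector (`gamma = 2.38 / sqrt(2 d)`, with a 10% chance of `gamma = 1` for
mode jumping), (b) the full group block, (c) a sweep of 2-d
(location, scale) subblocks, and (d) an interweaving move that proposes a
new (location, scale) for one randomly chosen group parameter while
rescaling all participant deviations with it
(`theta' = loc' + (theta - loc) scale'/scale`). For (d) the
hierarchical-prior ratio cancels the transport Jacobian exactly, so
acceptance depends only on the likelihood and the hyperprior; this move is
what lets the weakly identified group scales mix through the funnel they
form with the participant deviations — without it, split R-hat for the
scale parameters stays far above 1.1 at practical run lengths. During
burn-in, migration steps (probability 0.05 per iteration) cycle whole
chain states around a random ring of chains.

Defaults: `max(12, 3 d)` chains (21 for the 7-parameter basic model),
1000 burn-in and 1000 retained iterations, thinning 1. Convergence is
declared at split R-hat below 1.1 (`rhat()`); summaries use the
shortest-interval 95% HDI (`hdi()`). Runs are bit-reproducible given
`seed`. All settings are arguments, none are hard-coded.

Shrinkage behaves as a hierarchy should: a participant with few trials has
a posterior mean strictly between their isolated maximum-likelihood
estimate and the group mean (a constructed-data test asserts exactly
this ordering).

## Model comparison

WAIC is computed from trial-level pointwise log-likelihoods: `lppd = sum_i
log mean_s exp(ll_si)` with stable log-mean-exp, `p_waic = sum_i
var_s(ll_si)` with the S-1 divisor, `waic = -2 (lppd - p_waic)`. Trials
are the pointwise unit (each response is one categorical observation);
aggregating cells into single observations would change `p_waic`. Because
trials sharing a cell and response category have identical pointwise
values, fits store one column per (cell, category) with the observed count
as a weight — exactly equivalent to the trial-level matrix, at a fraction
of the memory. A single retained draw leaves the variance penalty
undefined; it is reported as 0 with a degeneracy flag and a warning.
`waic_table()` reports difference scores (winner 0, others positive),
flags differences of 10 or more as large, and breaks exact ties toward the
simpler variant (`EV`, then the constrained variants, then `UV_free`).

## The synthetic-experiment generator

`generator_config()` describes a study-test design (defaults: 67
participants, 768 test trials per condition across 2 sessions) or 6-/3-item
Sternberg designs (33 x 336 and 29 x 648 across 3 sessions) — the scale of
the experiments the generator emulates. Probes are split 50/50 between
targets and lures; target probes are balanced across serial positions to
within one trial (exactly when divisible). Group-level defaults echo
published group estimates for word and face recognition (SD ratios near
0.72 and 0.87 in the long-term design and stronger target-mean separation
for words than faces; in the short-term designs, ratios near 0.66/0.81 for
6-item lists and 0.48/0.83 for 3-item lists), with moderate
between-participant spread (0.3 on means and the criterion anchor, 0.1 on
the log free-SD, 0.2 on log-spacings), so simulated ROCs visually resemble
real ones.

Reaction times are a deliberate stand-in: nothing in the analysis models
RTs, they exist so RT filtering has something to act on. They are
log-normal (location `log(900)` ms, scale 0.35) truncated to the
300–4000 ms filter window, plus a configurable contaminated fraction
placed outside the window (default 2%, in line with the 1.5–3.3% exclusion
rates typical of such experiments). Consequently, passing tests say
nothing about realistic RT distributions, sequential effects, fatigue, or
non-Gaussian strength distributions — the generator realizes exactly the
hierarchical multinomial model the fits assume, which is the point of a
recovery study: it isolates the estimation machinery from model
misspecification.

## Numerical choices and degenerate inputs

Category probabilities are floored at 1e-12 before logs, so extreme tail
criteria cannot produce infinite log-likelihoods (at most it perturbs the
likelihood where the model already assigns essentially zero mass).
`filter_by_rt()` keeps both bounds (only strictly faster/slower responses
are excluded). Empty trial collections, zero-trial cells, `n_keep = 0`
runs, single-draw WAIC, and constant-chain R-hat (undefined, flagged
rather than thrown) all have defined behavior covered by tests. The
participant exclusion rule (drop a participant-condition cell at or below
chance accuracy 0.5, scoring responses 1–3 as "old") is a configurable
stand-in for study-specific exclusion judgments, not a reconstruction of
any particular study's.

## Problem sizes used in the checks

The recovery suite runs 20 replications of 8 participants x 150 trials
(500/500 iterations) and asserts at least 90% HDI coverage of the group SD
ratio and target mean; the headline recovery check uses 24 participants x
400 trials (1500/1500 iterations), a size at which the group SD ratio is
estimated to within a few percent. These sizes were chosen as the smallest
at which the hierarchy is well identified; scaling further up (e.g. to 67
x 768) only tightens the posteriors.

## Known limitations

* No dual-process, mixture, or exemplar likelihoods; zROC nonlinearity is
  not tested (inspect the overlays from `plot_roc_overlay()`).
* Conditions are fully independent — no cross-condition partial pooling.
* WAIC standard errors and stacking weights are not computed; only
  difference scores are reported.
* The sampler is random-walk-based (by design, for robustness to parameter
  correlations without gradients); very large hierarchies will mix more
  slowly than a gradient-based sampler would.
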