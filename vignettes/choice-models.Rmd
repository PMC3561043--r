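---
title: "Modelling choices in the bin-sampling gamble task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling choices in the bin-sampling gamble task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The task and what the package models

A subject faces a sequence of bins (urns). Each bin contains balls of $K$
colors ($K \in \{2, 5, 10\}$), color $k$ occurring with an unknown
probability $\theta_k$. The bin is played twice. In each stage, 10–14 balls
are drawn with replacement; only the payoff written on each ball is shown,
but a legend in the display links every color to its payoff, so the hidden
color behind an observed payoff can be inferred by inverting the legend.
After the draws, six gambles on one further ball are offered at prices drawn
uniformly between the stage's minimum and maximum payoff; four are decided
without knowing the outcome (active), two with the outcome known (control).
Between stage 1 (sampling) and stage 2 (resampling) the color probabilities
stay fixed but payoffs are re-assigned to colors, so evidence about *colors*
survives the boundary while evidence about *payoffs* does not. Probabilities
and payoffs are assigned independently, which makes payoff probability
orthogonal to payoff magnitude by design — the key property that lets one
separate probability learning from value.

`problearn` simulates this task (`task_design()`, `simulate_cohort()`),
generates choices from any model of the family, fits the models by maximum
likelihood, compares them by BIC, and derives the uncertainty regressors
used in event-related analyses.

## The model family

Every model scores a priced gamble and converts the score into a buy
probability by a logistic (softmax) rule
$q = \mathrm{logit}^{-1}(\beta_0 + \beta_1 \cdot EV)$. They differ in how
beliefs are formed and how payoffs are valued:

* **Belief formation.** Counts $n_k$ of inferred states follow a symmetric
  Dirichlet prior with concentration $\alpha_0$ per state; the point
  estimate after $t$ draws is the posterior mean
  $\hat p_k = (n_k + \alpha_0) / (t + K\alpha_0)$. The *hidden-state*
  learner (M2, M4, M5) keeps counts across the resampling boundary; the
  *observation* learner (M4a) resets them at every stage start (it learns
  payoff frequencies, which the legend change invalidates); the
  *no-learning* baseline (M4b) never updates, so $\hat p_k = 1/K$ always.
* **Reinforcement baseline (M3).** A delta rule bypasses probabilities and
  tracks the expected payoff directly: the first payoff of a stage sets the
  forecast $V$, and each later payoff $x$ updates
  $V \leftarrow V + \eta (x - V)$. The forecast restarts at both stage
  boundaries because stage-2 payoffs are new.
* **Valuation.** Linear models (M2, M3) use the net payoff $x - P$ itself.
  Prospect-theory models use the piecewise power value
  $v(x) = x^\alpha$ for $x \ge 0$ and $v(x) = -\lambda (-x)^\alpha$ for
  $x < 0$: one diminishing-sensitivity exponent $\alpha$ shared by gains and
  losses (this keeps M4 at exactly four parameters) and a loss-aversion
  multiplier $\lambda$. M5 additionally passes probabilities through the
  one-parameter inverse-S weighting
  $w(p) = p^\gamma / (p^\gamma + (1-p)^\gamma)^{1/\gamma}$.
* **Gamble score.** $EV = \sum_k w(\hat p_k)\, v(x_k - P)$ with the
  end-of-stage beliefs; for M3, $EV = V - P$.

The dataset log-likelihood sums $\log q$ over bought and $\log(1-q)$ over
passed *active* trials; control trials are excluded because the outcome is
known in advance and the decision does not express valuation under
uncertainty.

## Parameters, defaults and units

| parameter | meaning | default / generator value |
|---|---|---|
| $\alpha_0$ | Dirichlet prior concentration per state | 1 (uniform prior) |
| $\beta_0, \beta_1$ | logistic intercept, slope (logit units, logit per value unit) | generator: 0.95, 0.54 |
| $\lambda$ | loss aversion | generator: 2.57 |
| $\alpha$ | diminishing sensitivity | generator: 0.69 |
| $\gamma$ | probability-weighting curvature, fit within $[0.3, 2]$ | generator: 0.89 (M5) |
| $\eta$ | delta-rule learning rate in $[0, 1]$ | generator: 0.17 (M3) |

The generator defaults (`default_choice_params()`) are plausible pooled
estimates for this task class and are what the recovery studies use. Any
symmetric $\alpha_0$ yields the equiprobable prior mean $1/K$; the package
uses $\alpha_0 = 1$, under which the predictive probability of a state after
ten one-sided two-state draws is exactly $11/12 \approx 0.92$ or
$1/12 \approx 0.08$ — matching the extreme estimates such data produce.
$\alpha_0$ is exposed as an argument everywhere.

Two reconstruction choices matter and are deliberate:

* **Pre-update stimulus probability.** The "probability of seeing the
  evidence" attached to a draw is computed from the beliefs held *before*
  that draw is incorporated. The $1/12$–$11/12$ arithmetic above only works
  pre-update, and the pre-update reading matches the interpretation of rare
  stimuli as surprising.
* **Price-free prediction error.** The value prediction error of a draw is
  the change in $\sum_k \hat p_k\, v(x_k)$ caused by that single
  observation; no price enters because none is posted during sampling.

## What the simulator emulates — and what it does not

Defaults follow the study design: 9 bins per subject (three per $K$,
shuffled), 10–14 draws per stage, 6 choices per stage (4 active, 2 control),
prices continuous-uniform between the stage's payoff extremes, 23 subjects
(hence $23 \times 9 \times 2 \times 4 = 1656$ active choices, the scale of
the study's pooled fit). True probability vectors are skewed and span low
and high values: $(0.7, 0.3)$ for $K=2$, $(0.40, 0.25, 0.15, 0.12, 0.08)$
for $K=5$, a normalized geometric decay (ratio 0.75) for $K=10$, each
permuted uniformly over states per bin. Payoffs are distinct two-digit
integers; two pool widths (10–99 and 40–69) are cycled over bins so payoff
spread varies independently of payoff count. Choices are generated from the
softmax rule of a specified model.

Not emulated: reaction times, missed responses (real datasets may lose a
few trials, e.g. a pooled $n$ slightly below the nominal count), visual
stimuli, scanner timing (event onsets are a configurable synthetic
1 s-on/1 s-off timeline), and any within-subject parameter heterogeneity —
the generator uses one parameter set for the whole cohort. Passing recovery
tests on these simulations therefore shows the *estimator* is consistent
and the models are mutually discriminable at study scale; it does not show
that real subjects obey the generating model.

## Fitting: numerical choices

The likelihood is maximized by Nelder–Mead in an unconstrained space:
identity for $\beta_0, \beta_1$; $\log$ for $\lambda$ and $\alpha$; a scaled
logit onto $[0.3, 2]$ for $\gamma$ (keeps $w$ monotone); a logit for
$\eta$. Five restarts draw starting values from documented distributions
($\beta_0 \sim N(0,1)$, $\beta_1 \sim U(0.1,2)$,
$\lambda \sim U(0.5,3)$, $\alpha \sim U(0.3,1.2)$,
$\gamma \sim U(0.5,1.5)$, $\eta \sim U(0.1,0.9)$). The simplex runs at
relative tolerance $10^{-10}$ (up to 5000 iterations); the best restart is
then *polished* by restarting the simplex at its own solution at tolerance
$10^{-13}$ until the improvement falls below $10^{-11}$. The polish phase is
what brings the no-learning model's $(\beta_0, \beta_1)$ profile within
$10^{-6}$ of an IRLS logistic regression on the same fixed covariate. On
well-sized data the restarts agree to well under $10^{-2}$ log-likelihood
units. Buy probabilities are clipped to $[10^{-9}, 1-10^{-9}]$ so
log-likelihoods stay finite; model selection is by strict minimum BIC with
ties broken toward fewer parameters. Fits are bit-for-bit reproducible
given (dataset, seed).

Degenerate inputs are rejected early: probability vectors must sum to 1
(tolerance $10^{-9}$), payoff pools must hold at least $K$ distinct values,
fitting requires at least ten active choices per free parameter, and a
likelihood that is non-finite at every restart is an error rather than a
silent `NA`.

## Uncertainty regressors

For event-related analyses the package exports, per subject, a BIDS-style
events table (`build_event_table()`, `write_events_tsv()`): each draw is a
1 s stimulus event carrying its pre-update probability and value prediction
error; each choice is a decision event carrying the gamble's expected
value, the outcome entropy $-\sum_k \hat p_k \ln \hat p_k$ of the
end-of-stage beliefs and the binary choice entropy of the softmax buy
probability; each stage ends with a feedback event carrying the stage's
total net payoff. Entropies use natural logarithms (nats); any base only
rescales a regressor, which standardization absorbs. Modulators are
mean-centered within subject, the usual parametric-modulation convention.
For control trials the expected value is that of the known net payoff and
the outcome entropy is 0. Outcome entropy is computed from the selected
hidden-state model's point estimates (the model the data favor), not from
weighted probabilities.

## Study sizes used by the shipped analyses

The recovery studies run 50 replicates of 23 simulated subjects (1656
active choices each), the scale at which the models were designed to be
compared; the orthogonality check uses 5000 generated bins. The unit-test
suite exercises the same machinery on smaller cohorts.

## Known limitations

* Pooled fitting is the default (one parameter set across subjects);
  per-subject fits are possible by subsetting the session tables but no
  hierarchical estimation is provided.
* The full Dirichlet posterior is carried only through its mean; no
  posterior-spread term enters valuation.
* The weighting function is the one-parameter inverse-S family; separate
  gain/loss weighting and rank-dependent (cumulative) weighting are out of
  scope.
* M4b's expected values depend only on the payoff set and price, so its
  fitted slope compensates scale differences rather than learning — by
  construction, not a bug.
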