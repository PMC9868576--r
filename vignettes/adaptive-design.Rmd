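---
title: "Model-based adaptive design for intertemporal choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based adaptive design for intertemporal choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inducer)
```

## The problem

In an intertemporal choice task (ICT) a participant repeatedly chooses
between a smaller immediate reward and a larger delayed one. Behaviour is
summarised by a latent-variable discounting model: a value function maps
each reward/delay pair to a subjective value, and a logistic response
model maps the value difference to a choice probability. `inducer`
implements the full adaptive-design loop around such models: infer the
model from one run of choices, invert it in closed form to build a second
run whose trials *induce* prescribed choice probabilities, and validate
the model by cross-run out-of-sample prediction error.

## The model

The working value function is the modified hyperboloid

$$v(r, D) = \frac{r}{1 + \kappa D^s},$$

with discount rate $\kappa \in [0, 1000]$, delay scaling
$s \in [0, 1]$ and delays $D$ in days (note $\kappa$'s unit is
day$^{-s}$, so $\kappa$ values are only comparable at a common $s$). The
immediate option has zero delay, so $v_\text{imm} = r_\text{imm}$.
Choice follows

$$p_\text{imm} = \frac{1}{1 + e^{\beta (v_\text{del} - v_\text{imm})}},
\qquad \beta \in [0.001, 2],$$

an increasing function of the value advantage of the immediate option
with indifference at equal values. Seven comparison models (hyperbolic,
exponential, constant sensitivity, hyperboloid, quasi-hyperbolic,
double exponential, and a control with $\beta$ fixed at 1) share this
response model; their canonical value functions live in one registry
(`model_spec()`), so alternative parameterisations can be swapped in.
Bounds for the comparison models mirror the working model's analogues:
rates in $[0, 1000]$, shapes and weights in $[0, 1]$.

## Trial generation

Setting $p_\text{imm}$ to a target $p$ and solving for the immediate
reward gives the trial-generating condition

$$r_\text{imm} = \frac{r_\text{del}}{1 + \kappa D^s}
  + \frac{\log\frac{p}{1-p}}{\beta},$$

implemented by `solve_immediate_reward()`; feeding the result back
through the response model returns $p$ to machine precision, and a
property test holds this to $10^{-10}$ over random in-bound inputs.

The default grid (`design_grid()`) crosses delays
$\{7, 30, 90, 180, 365\}$ days with delayed rewards
$\{5, 10, 20, 50, 100\}$. Run A places one indifference trial
($p = 0.5$) per cell at each of four representative $(\kappa, s)$ pairs
— 100 trials; the quartet defaults to
$\kappa \in \{0.002, 0.01, 0.05, 0.2\}$ at $s = 1$, a configurable
shallow-to-steep spread, not normative values. Run B solves the
condition at nine targets $0.1, \dots, 0.9$ per cell — 225 trials.

Some parameter/stimulus constellations demand immediate rewards below
zero or above the delayed reward. The generator then adjusts the delay
iteratively — shorter delays raise the discounted value and hence the
solved reward, longer delays lower it; we take geometric (halving /
doubling) steps over integer days, because the solved reward is monotone
in delay and the admissible delays form an interval, until hitting the
bounds 1 and 365. Delay-adjusted trials still induce their target
exactly, since the reward is re-solved at the new delay. Only if no delay
works do the penny rules apply: negative rewards become 0.01 and rewards
tying the delayed one become $r_\text{del} - 0.01$ (money is decimal
currency; a "penny" is 0.01). Penny-clamped trials deviate from their
target; `generate_run_b()` therefore recomputes and stores each emitted
trial's `predicted_p`, which is the model's honest prediction for the
run.

## Inference

`fit_mle()` maximises the Bernoulli likelihood with box-bounded
L-BFGS-B from 20 seeded random starts (log-uniform over
$[10^{-4} \cdot \text{upper}, \text{upper}]$ for rates, uniform for the
rest); the start count and distribution are package choices. Per-trial
probabilities are clipped to $[10^{-10}, 1 - 10^{-10}]$ inside the
likelihood as well as in the prediction error, which keeps the objective
finite when parameters sit at bounds. A brute-force grid search over
$21^3$ parameter points serves as an independent oracle in the tests:
the optimiser must never return a worse likelihood. Data in which every
choice is identical are weakly identified; the fit is returned with a
`degenerate` flag rather than an error.

## Validation

Out-of-sample prediction error is the mean binomial deviance
(`binomial_deviance()`), $-2\log\hat\mu$ for immediate choices and
$-2\log(1-\hat\mu)$ for delayed ones, with the $0\log 0 = 0$ convention.
`cross_run_pe()` evaluates both cross-validation directions (run-B data
under run-A fits and vice versa) and decomposes run-B PE by target
condition; the trial-weighted condition PEs recompose exactly to the
overall PE. `aic()` provides the in-sample comparison, and
`count_best_models()` counts, per participant, every model within 0.01
deviance of the minimum — near-ties count multiply.

`induction_regression()` regresses observed on induced frequencies at
the group level (condition means) and per participant.
`homogeneity_ftest()` compares between-participant variances of
condition frequencies; the default p-value is two-sided, which is the
convention that reproduces the reference variance-ratio p-values this
statistic is checked against (a one-sided option is provided).
`reliability()` correlates $\beta$, $\kappa$, $s$ and the discount
factor at 90 days across runs, first removing pairs more than 3 scaled
MADs (consistency factor 1.4826) from the mean. That screen is taken
literally — distance from the *mean* — which makes it fragile under a
single extreme outlier (the outlier drags the mean until every point
trips the threshold); it is kept because it is the stated rule.

## Synthetic agents and what the simulations show

`simulate_choices()` draws i.i.d. Bernoulli choices from any zoo model;
`sample_population()` draws agents with log-uniform $\kappa$ and uniform
$s, \beta$; `end_to_end_experiment()` runs the whole two-run protocol,
with a master seed fanned out to per-agent, per-stage sub-seeds so every
stage is independently reproducible. Agents whose simulated run-A
discounted-choice rate falls outside $[5\%, 95\%]$ are excluded as
degenerate. The default population ranges ($\kappa \in [0.002, 0.2]$
log-uniform, $s \in [0.4, 1]$, $\beta \in [0.1, 1]$) span shallow to
steep discounting while avoiding all-one-choice behaviour.

Three canned studies quantify the protocol (problem sizes chosen to keep
each study in the low minutes on one core):

* `study_recovery()` (200 agents, 100 trials): the discount factor at 90
  days is recovered with $r > 0.9$ even though $\kappa$ alone recovers
  substantially worse — $\kappa$ and $s$ trade off along a ridge, but
  the factor they jointly determine is stable. This is why reliability
  claims should rest on discount factors, not raw $\kappa$.
* `study_model_selection()` (50 agents, full zoo, both runs): the
  generating model attains the lowest mean cross-validated PE, and PE
  picks the generating model for more agents than AIC does — in-sample
  criteria under-penalise the flexible relatives.
* `study_induction()` (50 agents): the headline fidelity check, with two
  variants. With `oracle_design = TRUE`, run B is generated from each
  agent's true parameters; observed condition frequencies then match the
  nine targets within binomial sampling noise and the observed-on-induced
  regression slope is 1. In the full protocol, run B is generated from
  run-A *fits*, and parameter-estimation noise at 100 trials attenuates
  induction: extreme targets regress toward 0.5 and the group slope
  lands around 0.8. This attenuation is a property of the protocol at
  this run-A length, not of the inversion (the emitted trials'
  `predicted_p` still track targets to $<0.003$); sharper induction
  requires more inference trials, consistent with the known difficulty
  of pinning down $\beta$ from short runs.

A fourth, `induction_ranges()`, defines the narrower population used for
the induction studies ($\kappa \in [0.02, 0.2]$, $s \in [0.8, 1]$,
$\beta \in [0.8, 1.6]$): steep enough discounting and high enough
sensitivity that every target is attainable inside the reward/delay grid
mostly by delay adjustment, keeping penny clamps — the only biasing
adjustment — rare.

What the simulations do *not* show: real participants are not stationary
Bernoulli machines. Session effects, lapses, reward-magnitude effects
and reaction-time structure are all outside the generative model, so
passing simulations demonstrate internal consistency of the machinery,
not behavioural validity in humans.

## Extensions

For history-dependent designs, values follow the Rescorla–Wagner delta
rule $v_t = v_{t-1} + \lambda (r_t - v_{t-1})$ (`rw_init()`,
`rw_update()`, `rw_trial()`). Indexing convention: $v_1$ is the initial
value and the first reward arrives on trial 2, so the expanded form
$v_t = \lambda \sum_{n=0}^{t-2} \gamma^n r_{t-n} + \gamma^{t-1} v_1$
($\gamma = 1 - \lambda$) holds exactly; the current trial's reward is
treated separately from the history term
$c = \lambda \sum_{n \ge 1} \gamma^n r_{t-n}$, and the numerical
round-trip test is the arbiter of this bookkeeping.
`rw_trial_reward()` inverts the updated-value sigmoid for the reward
that induces a target probability, given the opponent stimulus's reward,
the histories and the initial values; by default only stimuli that
receive a reward are updated, and the trial-level helper updates both.

For $K$-way choices under a softmax response model,
`softmax_trial_values()` solves the coupled conditions
$v_k = \log\big(\sum_{j \ne k} e^{\beta v_j}\big)/\beta +
\log\frac{p_k}{1-p_k}/\beta$. The system only determines values up to an
additive constant, so the gauge is fixed by anchoring $v_K = 0$; a
damped fixed-point iteration (damping 0.5) converges quickly and is
cross-checked in tests against the closed form
$v_k = (\log p_k - \log p_K)/\beta$. Whether $\beta$ is fitted or fixed
in these extensions is left to the user; the generators take it as an
argument.

## Numerical choices and limitations

* Probability truncation constant $10^{-10}$, applied in both the
  likelihood and the deviance.
* Optimiser: `optim`'s L-BFGS-B with default tolerances and
  finite-difference gradients; per-start termination status is recorded.
* Degenerate inputs (empty data, out-of-bound parameters, targets at 0
  or 1, zero-variance denominators) raise descriptive errors naming the
  offending quantity.
* Losses (negative rewards), magnitude effects, probability/effort
  discounting, reaction-time models and Bayesian/hierarchical estimation
  are out of scope.

## A worked example

```{r example, eval = FALSE}
params <- param_vector("modified_hyperboloid",
                       kappa = 0.05, s = 1, beta = 0.3)
discount_factor(params, 90)            # 0.1818
run_a  <- generate_run_a()             # 100 trials
choices <- simulate_choices(agent_spec(params, seed = 42), run_a)
fit    <- fit_mle("modified_hyperboloid", choices, seed = 1)
run_b  <- generate_run_b(fit)          # 225 trials, 9 target levels
```
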