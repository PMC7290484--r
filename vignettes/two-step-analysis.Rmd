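---
title: "Methods: the two-step task, the hybrid learner, and the crossover pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the two-step task, the hybrid learner, and the crossover pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twostepr)
```

This vignette is the package's own account of the science it implements:
the task environment, the hybrid dual-system learning model and its
likelihood, MAP estimation, the behavioral scores, the paired Bayesian
statistics, the dosing arithmetic, and the synthetic crossover cohort that
serves as the validation surface. It also records the numerical and design
choices that were genuinely open, and what the passing tests do and do not
establish about real data.

## The task environment

`task_config()` fixes the structure of the two-step task: two first-stage
options, two second-stage states with two options each, a common-transition
probability of 0.8 (first-stage option *j* commonly reaches state *j*; the
mapping is fixed within a session and recorded in the trial log), 250
trials in two equal blocks, outcomes from −4 to +5 points, a 2 s response
window, and a 5-point penalty for a missed response.

Each second-stage option's latent value performs an independent Gaussian
random walk (step sd 0.2) on [0, 1] with reflecting boundaries: an
overshoot past a bound is folded back by the overshoot amount
(`x → 2·bound − x`), iterated until the value is inside. The walk starts at
the midpoint of the interval — an unbiased choice; with sd-0.2 steps the
walk forgets its start within a handful of trials, and the long-run
marginal distribution is uniform on [0, 1] (checked by a 10,000-trial
histogram test against the brute-force walk).

Latent values are paid out through a linear quantization onto the ten
integers −4…+5: `points = floor(9·u + 0.5) − 4`. The mapping uses
round-half-away-from-zero explicitly, so that the midpoint latent value 0.5
maps to +1; base R's banker's rounding would map it to 0 and make the map
asymmetric around the center. The map is monotone and surjective (all ten
outcomes, including the 0 "nothing" outcome, are reachable); it is the
simplest such map and is configurable.

**Walk selection.** Shipped walks are pre-simulated so that the costlier
model-based strategy is guaranteed to pay off: `select_reward_walk()`
generates candidate walks and evaluates each by simulating a purely
model-based reference agent (ω = 1) and a purely model-free one (ω = 0) —
other parameters at the population medians (α 0.89, β 4.70, λ 0.48,
π 0.16) — 100 times each, keeping the walk that maximizes the model-based
agent's mean final-score advantage and insisting the advantage be
positive. Mean final-score advantage over a configurable simulation count
is this package's declared selection criterion. The packaged
`default_reward_walk()` was selected from 20 candidates at seed 1.

## The hybrid dual-system learner

Model-free values are learned by SARSA(λ). With all values starting at
`q_init` (default 0.5, the midpoint of the normalized reward scale), the
end-of-trial updates use the pre-update prediction errors

$$\delta_1 = Q_{MF}(s_2,a_2) - Q_{MF}(s_1,a_1), \qquad
  \delta_2 = r - Q_{MF}(s_2,a_2),$$

moving the chosen second-stage value by $\alpha\delta_2$ and the chosen
first-stage value by $\alpha\delta_1 + \alpha\lambda\delta_2$. Unchosen
values never move. Model-based first-stage values plan through the known
transition matrix,

$$Q_{MB}(a_j) = P_{common}\max_a Q_{MF}(s_{common(j)},a) +
               (1-P_{common})\max_a Q_{MF}(s_{other},a),$$

and first-stage choice applies a softmax with inverse temperature β to
$Q_{net} = \omega Q_{MB} + (1-\omega)Q_{MF}$ plus a stickiness bonus π for
the option chosen on the previous trial. Second-stage choice applies the
same softmax to the realized state's model-free values, without
stickiness.

Three conventions are deliberate choices where the published model
description leaves room:

* **Reward scale.** Points are normalized to [0, 1] via
  `(points + 4) / 9` before entering the learning rule. This keeps
  Q-values on a unit scale so that fitted β magnitudes are commensurate
  with the population values the generator targets (median β ≈ 4.7); a β
  fitted on raw points would be roughly nine times smaller.
* **Stickiness scope.** π applies only at stage 1, compared against the
  previous trial's stage-1 choice: the first-stage options persist across
  trials, whereas the second-stage option set depends on the realized
  state, so a stage-2 "repeat" indicator is not well defined. On the first
  trial the indicator is zero for both options.
* **Timeouts.** Missed-response trials contribute no likelihood terms,
  trigger no value updates, and do not advance the perseveration memory;
  they cost the configured penalty in the final score, and the following
  trial is not scorable for stay analysis. The generative simulator emits
  none (the model has no response-time process); the ingestion path
  accepts them.

The replay/likelihood and the generative simulator share one compiled core
(`src/replay.cpp`). Numerically, choice log-probabilities are accumulated
by log-sum-exp and each probability is computed by direct division rather
than as `1 − p`: at large β the complementary probability can be of order
e^−100 — far below the 2^−53 resolution of `1 − p` but comfortably inside
double range — and the subtraction would round it to an exact zero,
turning a finite log-likelihood into −∞. A pure-R, trial-by-trial
reimplementation in the test helpers serves as an independent oracle; the
two agree to better than ten significant digits on hand-constructed and
simulated sessions.

## MAP estimation, BIC, optimal choice rates

Each subject-session is fitted by maximizing the log posterior: the
session log-likelihood plus independent log prior densities. The default
priors are weakly informative and unimodal on each support — Beta(2, 2)
for ω, α, λ; Gamma(shape 3, scale 2) for β; Normal(0, 1) for π — a
deliberately mild regularization in the spirit of the empirical priors
commonly used for this model. All hyperparameters are arguments, and
`flat_priors()` gives maximum-likelihood behaviour (the MAP/MLE agreement
under flat priors is tested against a grid refinement).

Optimization is bounded L-BFGS-B from `n_restarts = 10` starting points
drawn from the priors (deterministic given the seed), with bounds
[ε, 1−ε] for the unit-interval parameters, [ε, 20] for β, and ±5 for π;
ties between restarts break to the lowest index. BIC is
`−2·logLik + 5·log(n_obs)` with `n_obs` the number of modeled choices —
two per completed trial, 500 for a complete session. This convention
matters for cross-study comparability of BIC magnitudes and is therefore
stated explicitly. Optimal choice rates replay the session under the
fitted parameters and report the fraction of completed trials whose chosen
option had the strictly highest decision value (stage 1: ω-mixed net
value; stage 2: the realized state's model-free value), crediting exact
ties 0.5.

## Behavioral scores

Stay probabilities tabulate, for every trial whose predecessor was also
completed, whether the first-stage choice was repeated, split by the
previous trial's outcome and transition. A "win" is strictly positive
points; the 0 outcome counts as a loss by default (the dichotomy used for
the published scores does not state how zero was classified; an
`exclude_zero` mode drops those trials instead). MF- and MB-scores are the
two linear combinations of the four cells (main effect of outcome, and
outcome × transition interaction); both are bounded by [−2, 2] by
construction. The final score is the summed points minus timeout
penalties; response-time summaries use the mean over completed trials
(median available).

## Paired statistics and Bayes factors

For each measure, `paired_compare()` reports the paired t test, a
Shapiro–Wilk check of the pair differences with the Wilcoxon signed-rank
test always computed alongside (flagged as required when normality fails
at p < 0.05), and a Bayes factor BF01 in the null-favouring direction.

The BF01 places a zero-centred Cauchy prior (default scale 1/√2) on the
standardized effect size and integrates the noncentral-t density over it;
the null marginal is the central t density. Bayes factors are only
comparable under a common prior: values computed under other default
priors (for instance the proprietary "diffuse prior" procedures of
commercial statistics packages) will differ numerically while agreeing in
their qualitative evidence categories (BF01 > 3 positive for the null,
1–3 anecdotal, ≤ 1 favouring the alternative). The implementation is
verified to 1e−6 against an independent quadrature oracle using the
inverse-gamma-mixture representation of the Cauchy prior. Correlation
analyses report Pearson r, Kendall τ, and Jeffreys's uniform-prior
correlation Bayes factor. No multiplicity correction is applied anywhere;
each measure is reported with its own uncorrected two-sided p.

Symptom ratings use the documented branching rule: paired Wilcoxon when
the sober ratings vary, one-sample Wilcoxon against zero when every sober
rating is zero, no test when both sessions are all zero. For n ≤ 10 the
signed-rank p-values are checked against exact enumeration of all 2^n sign
assignments.

## Dosing arithmetic

Total body water uses the Watson male equation
`TBW = 2.447 − 0.09516·age + 0.1074·height + 0.3362·weight` (liters);
several Widmark/Watson variants exist in the dosing literature, so the
estimator is a plain function that can be swapped. The peak-BAC prediction
is Widmark-style: `BAC‰ = dose_g/L_TBW · (1 − deficit) · 0.80 / 1.055`,
with the blood-water fraction (0.80) and blood density (1.055 g/mL) as
standard constants; with the protocol dose of 2.6375 g/L this yields
exactly 2.0 ‰ at a hypothetical zero resorption deficit, 1.6 ‰ at 20 %,
and 1.2 ‰ at 40 %. Beverage volumes use the serving definitions 14 g/50 mL
(brandy, 36 vol%) and 15 g/200 mL (red wine, 9.5 vol%).

## The synthetic crossover cohort

`generate_cohort()` emulates the study design: n subjects (default 25),
each simulated once "sober" and once "hungover" on one shared reward walk,
with session order balanced across subjects. True parameters are drawn
per subject from a population centred on medians realistic for strongly
model-based performance on this task (ω 0.83, α 0.89, β 4.70, λ 0.48,
π 0.16); the hungover session adds a configurable additive
`session_effect` per parameter (all-zero by default — the null world),
clamped to the parameter bounds.

The sampling families were chosen once to hit target quartiles around
those medians and then frozen: ω ~ Beta(4, 1) (quartiles ≈
0.71/0.84/0.93, targeting 0.70/0.83/0.90), α ~ Beta(6, 1),
β ~ Lognormal(log 4.7, 0.35), λ ~ Beta(0.7, 0.75) (λ spreads over nearly
the full unit interval with mass at both ends), π ~ Normal(0.16, 0.06). A
quantile test on 20,000 draws pins these choices. Response times are decorative
lognormals with means near 491/585 ms; they exercise the RT comparison
stage only and carry no model content. A synthetic AUDIT-like covariate
(rounded Normal(10.1, 2.8), clipped to 2–19) exercises the correlation
stage.

What the generator deliberately does **not** emulate: response-time
dynamics coupled to difficulty or conflict, timeouts and lapses, practice
or fatigue trends within a session, different stimulus sets between
appointments, and any true hangover mechanism — a "session effect" here is
a clean additive parameter shift. Passing tests therefore establish that
the pipeline is internally correct and well calibrated (it recovers known
parameters and holds its nominal error rates in the world the model
assumes), not that the model is adequate for any particular empirical
dataset.

`recovery_study()` generates, fits, and compares: per parameter it reports
the Spearman correlation between generating and recovered values, bias,
and RMSE. `power_curve()` asks what hungover ω-shift the design could
detect: for each shift magnitude it generates replicate cohorts, fits
them, and records how often the paired t on fitted ω rejects at α = 0.05
and how often BF01 < 1/3.

## Problem sizes and runtime choices

The validation suite runs at the design's own scale where that is cheap and
at reduced scale where fitting dominates: the recovery check uses 50
subjects × 250 trials × one session with 5 optimization restarts per fit;
the stay-signature checks use 100 sessions per agent type; walk
boundedness is checked over 10,000 independently seeded walks; t-test
calibration uses 1,000 replicate difference vectors of n = 25; the
acceptance script's cohort analysis uses the default 25 subjects × 2
sessions. Restart counts below the default trade a small risk of local
optima for runtime; the multi-start optimum is tested against a
5-points-per-axis grid oracle on full-size sessions.

## Known limitations

* The likelihood replays a single known transition structure; it does not
  estimate subjects' transition knowledge, and alternative model families
  (two learning rates, two temperatures, pure-MB/pure-MF variants) are out
  of scope.
* BF01 values are comparable across runs of this package but not
  numerically to Bayes factors computed under other default priors.
* MAP point estimates near parameter bounds (α, λ at 0 or 1) inherit the
  usual boundary bias; hierarchical shrinkage is not implemented.
* The λ parameter is weakly identified from 250 trials (its recovery
  correlation is the lowest of the five), which is a property of the
  design, not of the optimizer.
* Dosing covers male anthropometrics only, mirroring the protocol's scope,
  and predicts peak BAC only — no elimination time-course.
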