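---
title: "Dynamic Landmarking: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic Landmarking: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynlandmark)
```

This vignette is the package's own account of the method it implements: the
model and its assumptions, the tunable parameters and their defaults, what
the simulation engine emulates (and does not), and the numerical and design
choices that were genuinely open.

## The estimand problem

Consider a proportional-hazards model conditional on treatment $Z$ and a
covariate $U$,

$$ \lambda(t \mid Z, U) = \lambda_0(t)\, e^{\beta_Z Z + \beta_U U}. $$

If $U$ is prognostic ($\beta_U \neq 0$) and omitted, the treatment-only
model estimates a *marginal* hazard ratio that differs from $e^{\beta_Z}$
even under perfect randomization — the hazard ratio is non-collapsible.
Operationally, conditioning on survival up to $t$ selects against
high-$U$ subjects, faster in the arm with the higher event rate, so the
marginal hazard ratio drifts over follow-up ("built-in selection bias").
In a propensity-score-matched study a second failure mode exists:
omitting a covariate associated with *allocation* from the PS model leaves
the matched arms incomparable (confounding bias). Both distortions hide
inside a single reported hazard ratio; Dynamic Landmarking makes them
visible and distinguishable.

## The procedure

Given a matched cohort:

1. Sort by observed follow-up time (ties: events before censored, then by
   subject id — a deterministic rule so runs replay exactly).
2. Record step 0: the treatment-only Cox fit and the balance of every
   omitted covariate, measured by the sum of squared z-differences (SSQ).
3. Delete the earliest $M$ observations *regardless of event status*; the
   new time zero is the follow-up time of the latest deleted subject. The
   partial likelihood depends only on the ordering of times, so estimates
   are invariant to this shift; the landmark time is recorded because it
   carries the "conditional on survival to $t$" interpretation.
4. Refit, re-measure balance, repeat until the remaining data cannot
   support a stable fit.

Preconditions: independent censoring, proportional hazards with a
time-invariant conditional treatment effect, and at least one measured but
omitted covariate to track. A time-dependent treatment effect is
observationally indistinguishable from induced heterogeneity, so a drifting
trajectory can never prove *which* of the two is present; with tracked
covariates it can, however, say whether an omitted measured covariate is a
plausible culprit.

## Balance: z-differences and their χ² reference

For each omitted covariate the treated-minus-control difference is
standardized by the standard error of that difference (Welch form for
continuous covariates, two-proportion form for binary ones). Unlike the
standardized mean difference, a z-difference scales with $\sqrt{n}$, which
is what makes its squared sum χ²-calibrated: under balance, SSQ over $k$
independent components has expectation $k$. The classifier uses the
$\chi^2_k$ upper-α quantile as its imbalance reference.

Ordinal and nominal covariates need a choice, because only the continuous
and binary forms are fully specified by the published method:

- **ordinal**: tie-corrected Wilcoxon rank-sum standardization over the
  declared level order (mean 0, unit variance under exchangeability; df 1).
  On two-level data it agrees with the binary z to within a few percent
  (pooled vs unpooled variance).
- **nominal**: one indicator z per non-reference level against the first
  declared level (df = levels − 1).

Both live behind `z_ordinal()`/`z_nominal()` and can be swapped without
touching SSQ aggregation. Covariate *types are declared*, never inferred
(`covariate_spec()`, JSON sidecar): silently misreading ordinal as nominal
changes the χ² degrees of freedom. Sign convention is treated − control for
every kind; degenerate covariates (constant at the same value in both arms)
are recorded as `NA` with their df counted, and degeneracy at different
values is an error rather than an infinite z.

## Cox fitting

The marginal fit is the treatment-only Cox model (Breslow tie handling,
Newton iterations, relative tolerance 1e-9). For the pair-stratified model
$h_j(t\mid Z) = h_{0,j}(t) e^{\beta_Z Z}$ each matched pair has its own
baseline hazard; only *informative* pairs — the earlier observed time is an
event while the partner is still at risk — contribute, and for clean 1:1
discordant pairs with distinct times the stratified partial likelihood
maximum has the closed form

$$ \hat\beta_Z = \log(a/b), \qquad \mathrm{se} = \sqrt{(a+b)/(ab)}, $$

with $a$ ($b$) the number of informative pairs whose treated (control)
member fails first. The implementation uses this exact reduction — it is
the same estimator as the Newton fit, at a fraction of the cost across the
thousands of refits a simulation study performs — and falls back to the
generic stratified Newton fit whenever ties within a pair or irregular
strata make the reduction inapplicable. The test suite cross-checks the
reduction against the independent Newton implementation to 1e-8.

Ties have probability zero under the continuous simulation model; real
data get Breslow handling. A monotone likelihood ($a = 0$ or $b = 0$, or
$|\hat\beta| > 15$) is flagged as non-convergence and terminates the
landmark loop rather than producing a spurious estimate. Estimates are
invariant to shifting or scaling the time axis (tested to 1e-12), which is
what justifies the landmark time-zero reset.

## Matching

The propensity score is fitted by maximum-likelihood logistic regression;
separation and collinearity abort with an explanatory error rather than
returning degenerate scores. Matching is greedy 1:1 nearest-neighbour on
the logit PS without replacement, caliper 0.2 × SD of the logit PS. Three
details are conventions the published method leaves open:

- the caliper SD is computed on the **pooled** (all-subject) logit PS — the
  common convention for this caliper;
- treated subjects are processed in **seeded-random order** (the order is
  recorded in the result for replay); PS-sorted processing would introduce
  order artefacts, and the data order is arbitrary;
- exact distance ties go to the smaller control id, for determinism.

After deletions begin, matched partners of deleted subjects are *retained*:
their singleton strata contribute nothing to the stratified likelihood but
still count for balance, which is measured with the unpaired two-group
formulas on all remaining subjects. A `drop_orphans` option removes
partners for sensitivity analysis.

## The simulation engine

The generator emulates a non-randomized cohort: $X, U$ standard normal with
correlation $\rho_{XU}$ (Cholesky construction), allocation
$\mathrm{logit}(p) = \alpha_0 + \alpha_X X + \alpha_U U$, Weibull
proportional-hazards event times
$h(t) = \gamma \lambda t^{\gamma-1} e^{\beta_Z Z + \beta_X X + \beta_U U}$
drawn by inverse transform, and exponential censoring. Defaults are the
strong-confounding reference: $n = 5000$, $\alpha_0 = -1.21$,
$\alpha_X = \beta_X = \beta_Z = \log 3$, $\lambda = 0.01$, $\gamma = 1.5$.
The zero pattern of $(\alpha_U, \beta_U)$ classifies $U$ as independent,
prognostic factor, instrument, or confounder (`covariate_role()`).

Two reproducibility notes. First, direct integration of the stated
allocation model gives ≈ 27% treated at $\alpha_0 = -1.21$ (with
$\alpha_U = 0$), slightly above the ≈ 24% the reference design describes;
the package keeps the stated parameters and reports the achieved fraction
rather than forcing agreement. Second, the mapping from an exponential
censoring *rate* to a censoring *proportion* depends on the whole
event-time model, and the commonly quoted parameter–proportion pairings are
not reproducible from the stated model (a rate of 0.2 censors far more than
10% here). `calibrate_censor_rate()` therefore bisects the rate against a
large probe cohort (n = 1e5, fixed probe seed, shared uniforms so the
censored fraction is monotone in the rate) until the achieved proportion is
within ±1% of target; every "10% censoring" scenario in tests uses a
calibrated rate, and the achieved value travels with the result.

All randomness descends from one master seed: replicate $r$ uses a child
seed drawn deterministically from the master (`child_seeds()`), and the
matching order consumes the same per-replicate stream, so any replicate can
be regenerated in isolation.

What the generator does *not* emulate: covariate-dependent or
administrative censoring, time-varying covariates or effects, competing
risks, non-normal covariates, and more than one omitted covariate at a
time. Passing tests therefore demonstrate the diagnostic's behaviour under
clean proportional hazards with independent censoring — they do not certify
performance when those assumptions fail, which is exactly the situation the
method itself cannot disentangle.

## Diagnostics and thresholds

The classifier follows a two-step reading: first the effect trajectory,
then (only if it shifts) the SSQ trajectory. All evidence is evaluated on
the first 50% of deletion, where the selection signal concentrates and
estimates are still stable. The published scheme is qualitative; the
package makes each branch operational with explicit, configurable
thresholds:

- **shift**: |log HR at the step nearest 50% deletion − log HR at step 0|
  > 2 × SE(step 0). The SE unit makes the rule scale-free across sample
  sizes; 2 corresponds to the usual Wald criterion. A least-squares slope
  over the first half is reported as supporting evidence.
- **initial imbalance**: step-0 SSQ above the χ²_k 0.99 quantile
  (α = 0.01, conservative because the SSQ is inspected post hoc).
- **rising SSQ**: positive least-squares slope of SSQ against deleted
  fraction over the first half (with a numerical-zero guard so an exactly
  constant trajectory does not classify as rising).

These defaults are screening thresholds, not a calibrated test — the method
is a diagnostic, and no formal error rate is claimed. When several
covariates are omitted at once, a confounder's z dominates the joint SSQ;
`diagnose_covariates()` therefore reruns the classification per covariate,
reusing the shared Cox trajectory (which does not depend on the balance
set) and extracting each covariate's own SSQ trajectory from the per-step
records. One consequence worth knowing: when *any* omitted covariate drives
a real shift, the shift applies to every per-covariate run, so an
uninvolved noise covariate classifies as "unmeasured source" (shift without
its own imbalance signal) rather than "no bias" — the imbalance columns,
not the shift flag, are what single out the culprit.

## Numerical and operational choices

- **Deletion step** `M`: default 1% of the analysis set (≈ 100 steps),
  configurable as a count or fraction. The x-axis of the diagnostic is the
  percentage of subjects remaining, so the default gives 1%-spaced points.
- **Stop rule**: remaining n < 100, events in either arm < 5, informative
  pairs < 10 (stratified), or a non-converged fit; each threshold
  configurable. Monte-Carlo runs in the tests and `run_scenario()` stop at
  40% remaining, since the classifier only consumes the first half — the
  default in `dynamic_landmark()` runs to the convergence limits.
- **Aggregation across replicates** (`run_scenario()`): trajectories end at
  different sizes, so curves are linearly interpolated onto a common
  1%-remaining grid before averaging; classification tallies and failed
  replicates (excluded, counted) are reported alongside.
- **Problem sizes**: the simulation-facing tests use 100 replicates of
  n = 5000 for the four canonical scenarios and 200 replicates for the
  matched-sample-size check, with smaller cohorts (n ≤ 2000, 20–60
  replicates) for property-style checks. These are the package's chosen
  desk-scale defaults; a full 500-replicate study is a `reps` argument
  away.

## Known limitations

- The shift detector compares two highly correlated estimates; its SE unit
  is the step-0 SE, so it is a screening rule, not a test with a controlled
  false-positive rate.
- Ordinal/nominal z-differences are this package's constructions (rank and
  indicator forms); other reasonable choices would change SSQ df-for-df
  only slightly but are not implemented.
- No competing risks, interval censoring, time-varying covariates, PS
  weighting, or k:1/optimal matching.
- With correlated omitted covariates the decision table's branch semantics
  blur (partial matching through the correlated included covariate); the
  classifier is derived for the uncorrelated case.
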