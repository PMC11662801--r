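# dynlandmark

Post-hoc bias diagnostics for hazard ratios from propensity-score-matched
survival analyses, by *Dynamic Landmarking*.

## The problem

In a non-randomized comparison of two treatments with a time-to-event
outcome, the usual pipeline is: estimate a propensity score (PS) by logistic
regression, form 1:1 matched pairs, and fit a treatment-only Cox model
(often stratified by matched pair) to report a hazard ratio. Two distinct
things can silently distort that number:

- **Confounding bias** — a covariate associated with both treatment
  allocation and outcome was left out of the PS model, so the matched groups
  are not actually comparable.
- **Built-in selection bias** — a *prognostic factor* (associated with the
  outcome only) was omitted from the Cox model. Because the hazard ratio is
  non-collapsible, conditioning on survival up to *t* progressively depletes
  high-risk subjects at different rates in the two arms, and the estimated
  hazard ratio drifts away from the conditional effect even though the
  groups were perfectly balanced at baseline.

The hazard ratio itself is a single number and offers no hint of either
problem. Dynamic Landmarking turns it into a *trajectory*: sort the matched
cohort by follow-up time, repeatedly delete the earliest `M` observations
(events and censored alike), move time zero to the follow-up time of the
latest deleted subject, refit the treatment-only Cox model, and — in
parallel — re-measure the balance of every *omitted* covariate with the sum
of squared z-differences,

```
SSQ = sum z_con^2 + sum z_bin^2 + sum z_ord^2 + sum z_nom^2 ,
z_con = (x̄_T − x̄_C) / sqrt(σ̂²_T/N_T + σ̂²_C/N_C),
z_bin = (p̂_T − p̂_C) / sqrt(p̂_T(1−p̂_T)/N_T + p̂_C(1−p̂_C)/N_C),
```

which under balance is approximately χ²_k for k independent components.
The joint behaviour of the two trajectories separates the two biases:

| effect trajectory | initial SSQ | SSQ over first 50% | reading |
|---|---|---|---|
| flat | small | — | no bias indicated |
| flat | large | — | omitted instrument |
| shifts | large | — | **confounding** |
| shifts | small | rising | **built-in selection** |
| shifts | small | flat | unmeasured source |

The package implements the full pipeline (simulation engine, PS estimation,
greedy caliper matching, z-differences/SSQ, marginal and pair-stratified Cox
fits, the landmark loop, and a rule-based classifier for the table above)
in a tidyverse idiom: tibbles in and out, `tidy()`/`glance()` accessors,
`autoplot()` figures.

## Worked example

Simulate a matched study in which a strong prognostic factor `U`
(log-hazard effect log 3) is omitted from both the PS model and the Cox
model, then diagnose it:

```r
library(dynlandmark)

cfg <- scenario_config(n = 5000, alphaU = 0, betaU = log(3),
                       betaZ = log(3), seed = 11)
cohort  <- simulate_cohort(cfg)
matched <- match_cohort(cohort, ps_covariates = "X")

fit_cox_pair_stratified(matched)
#> pair_stratified Cox fit: log HR = 0.7587 (HR 2.135), se = 0.0618,
#>   95% CI [0.6375, 0.8799]
#> n = 2408, events = 2408, informative pairs = 1204

traj <- dynamic_landmark(matched, omitted = "U")
classify_bias(traj)
#> Bias diagnosis: builtin_selection_suspected
#>   shift: yes (|d log HR| = 2.18 SE units, slope -0.299)
#>   initial SSQ: 2.59 on k = 1 df (p = 0.107); first-half trend 40.852
#>   Systematic shift with initially balanced but increasingly imbalanced
#>   omitted covariates: condition the Cox model on the flagged prognostic
#>   factor(s) for a subject-specific effect.

autoplot(traj, true_log_hr = log(3))   # dual-axis trajectory figure
```

The step-0 estimate (0.76) already sits below the simulated conditional
effect log 3 ≈ 1.10 — that gap *is* the built-in selection bias — and the
trajectory drifts further as low-risk subjects take over, while the SSQ of
the (initially balanced) omitted factor climbs steeply: the signature of an
omitted prognostic factor, not of confounding. With `alphaU = log(3)` the
same code flags `confounding_suspected` with an extreme step-0 SSQ instead.

`balance_report()` works equally on real cohorts read with `read_cohort()`
(CSV plus a JSON covariate-type sidecar; types drive the χ² degrees of
freedom). A thin command-line wrapper with `simulate`, `match`, `balance`,
`landmark` and `diagnose` subcommands lives in `inst/cli/dynlandmark.R`.

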