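# pmflex

Simulation and analysis tools for **prospective memory (PM)** dual-task
experiments in which the difficulty of an ongoing visual search task ramps
up or down *within* a trial. The package is aimed at cognitive
neuroscientists who study how people shift between **proactive control**
(holding a delayed intention in working memory and monitoring for its cue,
at a reaction-time cost to the ongoing task) and **reactive control**
(relying on cue-triggered retrieval, with little or no cost), and who want
a tested, reproducible implementation of the full analysis chain together
with a synthetic-cohort generator for power analysis and parameter-recovery
studies.

## What it computes

For a session of trials whose search difficulty (15 levels defined by the
distractor-to-target minimum angle and distractor variance) increases,
decreases or stays fixed probe by probe:

- **PM cost** per 2 s probe: the ongoing-task RT on a PM trial minus the
  participant's mean correct non-PM RT at the same difficulty level and
  practice half (a 15 × 2 baseline table),
  `cost(probe) = RT(probe) − baseline(level, half)`.
- **PM cost slope** per trial, the within-trial shift of strategy:
  `slope = [mean(cost, probes n−3…n−1) − mean(cost, probes 1…3)] / n`,
  expressed in ms/s (positive = shift toward proactive control). Trials
  with below-chance (< 50%) ongoing-task accuracy are excluded.
- **Per-trial model selection**: first/second/third-order polynomial fits
  of cost against difficulty, compared by AICc
  (`AICc = AIC + 2k(k+1)/(n−k−1)`) and Akaike weights
  (`w_i = exp(−Δ_i/2) / Σ_j exp(−Δ_j/2)`), plus a super-subject bootstrap
  selection analysis on within-participant z-scored costs.
- **Bootstrap inference**: logistic regressions of PM accuracy on PM cost
  slope per trial direction, with participant-level resampling (percentile
  CIs and two-sided bootstrap p-values), partial regressions against
  nuisance covariates, and wAIC comparison of behavioral, neural and
  combined predictor models.
- **PM intention evidence (PM EV)**: a simplified decoding stage —
  one-vs-rest L2-penalized logistic classifiers (penalty = 50) over
  face/scene/ongoing/rest classes, ANOVA feature screening inside each
  leave-one-run-out fold, scrambled-label chance calibration — yielding
  per-trial `EV = evidence(target category) − evidence(nontarget category)`.

A synthetic-cohort generator (`simulate_cohort`, `simulate_neural`)
produces behavioral sessions and class-templated neural feature matrices
from a latent strategy trace with known ground-truth parameters, so every
statistic above can be validated by parameter recovery.

## Worked example

```r
library(pmflex)

cfg <- pm_config(seed = 4, n_participants = 10, n_blocks = 3,
                 n_neural = 3, n_boot = 200)
run <- run_pipeline(cfg)
run
#> pmflex run 1b204b33 seed 4
#> 10 participants, 300 trials (4.7% excluded)
#> condition mean PM cost slopes (ms/s):
#>   direction mean_slope
#> 1       dec       1.98
#> 2       fix       1.02
#> 3       inc      -1.08
#> Bootstrap logistic regression of PM accuracy on PM cost slope
#>               term estimate boot_mean  ci_lo    ci_hi    p
#> 1         beta_dec   0.0197    0.0263 -0.042  0.12617 0.53
#> 2         beta_inc  -0.0508   -0.0584 -0.126 -0.00306 0.04
#> 3 beta_interaction   0.0705    0.0847 -0.015  0.20444 0.14
#> dropped iterations: 0
```

Reading the output: decreasing-difficulty trials show a positive mean PM
cost slope (+2.0 ms/s — participants shift toward proactive control as
resources free up) and increasing trials a negative one; `beta_dec` is the
logistic coefficient linking that slope to PM accuracy on decreasing
trials, and `beta_interaction` tests whether the slope-accuracy link
differs between decreasing and increasing trials. At this demonstration
scale (10 participants, 200 bootstrap iterations) the CIs are wide; at
full cohort scale (78 participants, thousands of iterations) the same
pipeline recovers the planted positive `beta_dec` and interaction reliably.

Individual stages are plain functions on data frames —
`generate_session()`, `simulate_cohort()`, `filter_responses()`,
`compute_baselines()`, `probe_costs()`, `cost_slope()`,
`fit_trial_polynomials()`, `slope_accuracy_model()`, `crossvalidate()`,
`pm_intention_evidence()` — see the methods vignette
(`vignettes/pmflex-methods.Rmd`) for the model and its assumptions.

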