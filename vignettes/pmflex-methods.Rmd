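---
title: "Measuring dynamic prospective-memory strategy shifts with pmflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring dynamic prospective-memory strategy shifts with pmflex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmflex)
```

## The problem and the paradigm

Prospective memory (PM) — remembering to execute a delayed intention at
the right moment — can be served by two control strategies. *Proactive
control* keeps the intention in working memory and monitors the
environment for its cue; it is effective but expensive, and the expense is
visible as slowed reaction times (RTs) on whatever else one is doing.
*Reactive control* leaves the intention in episodic memory and counts on
the cue to trigger retrieval; it is cheap but more fragile. `pmflex`
implements an analysis chain for a paradigm built to observe *graded,
moment-to-moment* shifts between these strategies: participants perform a
visual search task (find the rightward horizontal arrow among oriented
distractors) whose difficulty ramps up, ramps down, or stays fixed one
level per 2 s probe, while also watching for the reappearance of a PM
target image (a face or a scene) that always ends the trial.

Search difficulty is parameterized by two distractor properties: the
minimum angular distance of distractors from the (horizontal) target —
one of 5, 15, 25, 45, 65, 75 degrees — and the maximum variance of
distractor orientations around that minimum — 10, 20 or 40 degrees.
Crossing these and excluding combinations whose sum exceeds the 90-degree
vertical plane leaves 15 conditions (`build_difficulty_table()`). The
reduced pilot parameterization, which stops at a 65-degree minimum,
leaves 14. The
mapping of the retained pairs onto ordinal levels 1–15 is not dictated by
the parameterization itself; `pmflex` orders by descending minimum
distance, then ascending variance, which makes the RT/accuracy gradient
monotone in level, and exposes a `permutation` argument for any other
ordering.

Five within-trial trajectories are used (`make_trajectory()`): increasing
from level 1, increasing from 8, fixed at 8, decreasing from 8, decreasing
from 15, with one step per probe and clamping at the endpoints. Each block
crosses the five trajectories with three PM-target types (face, scene,
none) exactly once; five trials per block are short "catch" trials (fewer
than eight probes) that keep attention up early in trials.

## The behavioral statistic

The central measurement is the **PM cost**: the RT paid on a PM trial
relative to a matched baseline without the intention. Baselines are the
mean correct non-PM-trial RT per difficulty level, computed separately for
the early and late halves of the session to absorb practice effects —
a 15 × 2 table per participant (`compute_baselines()`). Responses faster
than 300 ms are discarded as carry-overs from the previous probe
(`filter_responses()`; the 300 ms boundary itself is kept, as the rule is
"faster than"). Each PM-trial probe then gets
`cost = RT − baseline[level, half]` (`probe_costs()`).

The **PM cost slope** summarizes how strategy moved within one trial: the
mean cost of the last three probes before the target reappears (the final
probe itself is excluded — the target is on screen) minus the mean cost of
the first three probes, divided by the trial's probe count
(`cost_slope()`). The quotient is divided by the 2 s probe duration and
reported in ms/s, so the number reads as an RT-cost drift rate; this
extra normalization is a package convention and is stated wherever slopes
are printed. Trials below 50% ongoing-task accuracy are excluded as
inattentive (`summarize_trials()`). Two choices here are deliberately
configurable because the convention is not uniquely determined: windows
are defined on calendar probe positions using whatever correct-response
costs they contain (at least one per window by default; `min_window_n = 3`
requires complete windows), and baselines can optionally use all responses
rather than correct ones only.

## Per-trial model selection

Whether strategy shifts *gradually* is asked by fitting first-, second-
and third-order polynomials of cost against difficulty separately per
trial (`fit_trial_polynomials()`) and comparing them with AICc. An
all-or-none strategy flip would appear as a cubic winner; a graded shift
as a linear one. The information criteria use the Gaussian-likelihood
form `AIC = n·ln(RSS/n) + 2k` with `k = order + 2` (the error variance is
counted; since every comparison is within a trial, the convention only
shifts all scores equally, and `k_extra` can change it). The AICc
small-sample correction `2k(k+1)/(n−k−1)` is undefined at `n ≤ k + 1`;
such models are disqualified rather than scored infinite. Fixed-difficulty
trials have a constant regressor and are excluded from difficulty fits.
Two corroborating analyses guard against the small-n bias toward simple
models: plain AIC, and a super-subject bootstrap
(`bootstrap_model_selection()`) that z-scores costs within participant,
pools all trials, and on each iteration selects the best order for a
50-trial sample of each trajectory type (fixed trials are regressed on
probe position there, since their difficulty never varies — a package
convention, as no difficulty regressor exists for them).

## Linking strategy shifts to PM accuracy

Because a session yields relatively few PM outcomes per participant,
inference pools trials and resamples *participants* with replacement
(`bootstrap_participants()`): each of the (by default 10,000; 2,000 in
the tests) iterations draws a full-size cohort, pools its trials, and
refits pooled fixed-effect logistic regressions of PM hit on PM cost
slope within each trial direction plus a slope × direction interaction
model (`slope_accuracy_model()`). Percentile 2.5/97.5 quantiles give the
CI; the two-sided bootstrap p is `2·min(P(β ≤ 0), P(β ≥ 0))`, floored at
`1/n_iter`. Iterations with (quasi-)separated fits are dropped and
counted, and a run aborts if more than 5% drop. `partial_r2()` residualizes
the slope and the outcome on a nuisance covariate (mean ongoing RT, mean
accuracy, mean cost, or raw RT slope) to show the slope's unique
contribution. `compare_predictor_models()` extends the comparison to the
neural metric: per bootstrap iteration it fits all candidate logistic
models over slope, mean PM intention evidence and direction, selects the
best behavior-only, best neural-only and the full combined model, and
converts their AICs to Akaike weights, summarized by medians, paired
Wilcoxon tests and median weight ratios.

## The decoding stage

The neural analysis is a deliberately simplified, format-agnostic
pattern-classification stage operating on a time-point × feature matrix
sampled once per 2 s probe. Labels (face / scene / ongoing-task / rest)
are shifted forward by two samples to offset hemodynamic lag, and the
final probe of each trial is excluded from training. Within each
leave-one-task-run-out fold — localizer data always stay in training —
features are z-scored, screened by a one-way ANOVA across the four
classes (p < 0.05; implemented as a vectorized F-test, identical to
per-feature `aov()` at far lower cost), and one-vs-rest L2-penalized
logistic classifiers are trained (`penalty = 50`, interpreted as the
weight on the squared-coefficient term of the unnormalized loss and
mapped to glmnet's ridge `lambda = 2·penalty/n`; inverse-strength
conventions can be configured through `penalty`). Evidence is each binary
model's probability-scale output, so the four values need not sum to one;
the prediction is the evidence argmax with ties broken in the fixed order
face, scene, og, rest. Chance is calibrated empirically by permuting
labels within runs and rerunning the pipeline (`scrambled_baseline()`);
on balanced classes the distribution centres on 25%. **PM intention
evidence** is `evidence(target) − evidence(nontarget)` per time point,
averaged per trial (`pm_intention_evidence()`), with the final probe
excluded by default for consistency with training.

## What the synthetic cohort emulates

`simulate_cohort()` generates sessions from a latent strategy trace
θ ∈ [0, 1]:

- Baseline RT rises linearly from 0.70 s (level 1) to 1.25 s (level 15),
  and accuracy falls from 0.97 to 0.62, matching the observed gradient of
  the paradigm (hardest-level accuracy above chance, RTs below the 1.9 s
  deadline). Residual RT noise is 0.15 s; draws are truncated below at
  300 ms and draws beyond the deadline become omissions.
- On PM trials, θ expresses itself as an additive RT cost
  `θ · cost_amplitude · decay(level)` with `cost_amplitude = 0.2` s and
  `decay(level) = 1 − (level − 1)/14`: full proactive engagement costs
  about 0.2 s on the easiest search and nothing on the hardest, which
  reproduces the fixed-difficulty pilot contrast (≈ 0.13 s at an easy
  level vs ≈ 0.03 s at a hard one) and the declining cost-by-difficulty
  profile. The multiplicative attenuation is a generator design choice:
  the empirical phenomenon is the decline, not its mechanism.
- θ starts at 0.35 and drifts linearly at a condition mean rate
  (+0.04/probe decreasing, −0.08/probe increasing, +0.03/probe fixed,
  clipped to [0, 1]) plus a per-trial Gaussian jitter (`drift_sd = 0.05`).
  The jitter is essential, not cosmetic: without trial-level variability
  the strategy at target onset is a deterministic function of condition
  and trial length, and no within-condition covariance between measured
  slope and PM outcome — the quantity the inference stage estimates —
  would exist to recover. The asymmetric drifts produce the observed
  slope asymmetry (decreasing-trial slopes larger in magnitude than
  increasing-trial ones) because the difficulty attenuation suppresses
  cost expression at the hard end of increasing trials.
- The PM hit at target reappearance is Bernoulli with probability
  `reactive_floor + (1 − reactive_floor) · plogis(pm_intercept +
  pm_slope_gain · θ_final)` (defaults 0.45, −1.4, 4). The floor encodes
  reactive retrieval succeeding without proactive engagement; the
  logistic term rewards proactive engagement at the moment the target
  appears. Defaults land overall PM accuracy near 75% and ongoing
  accuracy near 80%, inside the descriptive ranges of the paradigm.
- `simulate_neural()` draws one Gaussian template per class and emits, at
  each sample, the template of the event two samples earlier (the
  hemodynamic lag the label shift undoes), scaled by `snr`, plus the
  PM-target template scaled by `coupling · (θ̄ − 0.5)` on PM probes, plus
  unit noise. Runs are blocks; encoding periods, one guard sample per
  rest interval and run lead-ins are unusable.

Known departures from real data, and hence limits on what green tests
show: RT noise is Gaussian and homoscedastic (real RT distributions are
right-skewed); the hit model couples accuracy to θ the same way in every
condition, so the generator produces an accuracy gradient across trial
directions where real cohorts showed none (the dissociation between
equal accuracies and direction-specific slope effects is a feature of
human data this generator does not reproduce); fMRI noise is white with
an instantaneous two-sample lag rather than autocorrelated and
convolved; and no speed–accuracy trade-off, fatigue or feedback dynamics
are modelled.

## Numerical choices and degenerate inputs

Exact-fit residual sums of squares are floored at 1e-10 before taking
logs, which lets a planted noiseless polynomial win without producing
infinite criteria. Circular orientation distance uses
`min(|Δ|, 360 − |Δ|)`; the anti-pop-out resampling gives up after 100
attempts per slot and relaxes that slot with a warning. Empty baseline
cells fall back to the same level's other practice half (flagged), never
to neighbouring levels. Session probe-count balance across PM-target
types is exact for block counts divisible by three (shared length
multisets within three-block spans) and approximate otherwise. Bootstrap
logistic fits flag separation by the glm warning or coefficients beyond
±25 on the predictor scales used here. All generators consume explicit
seeds; cohort members get seeds drawn once from the master seed, and
pipeline stages derive seeds by fixed offsets so stages can be re-run
independently.

## Problem sizes in the shipped tests

The test suite exercises the pipeline at reduced but statistically
meaningful scales chosen once: cohorts of 10–30 participants and 200–2,000
bootstrap iterations for unit and calibration tests, 20 replicates of the
full 78-participant, 2,000-iteration recovery analysis for the
sign-recovery check, 200 scrambled-label permutations for the chance
calibration, and 100 replicates of a 30-participant null cohort for CI
coverage. The same code paths scale to the full 10,000-iteration analyses
via their `n_iter`/`n_perm` arguments.
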