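---
title: "Simulating and scoring the Doors approach-avoidance conflict task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and scoring the Doors approach-avoidance conflict task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doorsim)
```

## The task and its behavioral model

The Doors paradigm presents a sequence of doors. Each door offers a
potential gain of $g \in \{1,\dots,7\}$ coins against a potential loss of
$l \in \{1,\dots,7\}$ coins. The participant expresses willingness to
engage on a continuous proximity scale $x \in [0, 100]$ (0 = full
avoidance, 100 = full approach, start position 50). Proximity maps
linearly onto the probability that the door opens,

$$p(\text{open}) = x / 100,$$

and an opened door delivers the gain or the loss with equal probability;
a closed door delivers nothing. One run crosses every $(g, l)$ cell
exactly once (49 trials, random order); sessions comprise 2 or 3 runs.
Accumulated coins convert to money in the paid variants.

The behavioral indices are per-subject ordinary-least-squares
coefficients from regressing chosen proximity on the mean-centered
magnitudes of potential gain ($\beta_{Gain}$, gain approach), potential
loss ($\beta_{Loss}$, active loss avoidance), and conflict
($\beta_{Conflict}$, conflict sensitivity), where conflict is

$$c = 7 - |g - l|,$$

maximal (7) when the magnitudes match and minimal (1) at extreme
disparity. Relatively low $\beta_{Gain}$ operationalizes passive
avoidance: forgoing rewards because harm is also possible.

## What the simulator assumes

The environment uses the exact linear opening map $p = x/100$; the
deployed task described its mapping as approximate, which we attribute
to input-device granularity rather than a different functional form.
Trial schedules are independent uniform permutations of the 49-cell
factorial per run. Outcome draws use a single RNG stream per session, so
a session is a pure function of its seed. The 5–7-coin initial award is
tracked for display but excluded from the bonus by default (it did not
count toward task earnings), with a configuration switch to include it.
Keyboard and joystick delivery are modeled identically at the level of
the final chosen proximity; within-trial movement dynamics are out of
scope.

## Agents

Agents are testing instruments with known ground truth, not claims about
how participants compute. Three policies are provided:

* **Linear** (`act_linear`): $x = b_0 + w_g (g - 4) + w_l (l - 4) +
  w_c (c - 33/7) + \varepsilon$, clamped to $[0, 100]$, with
  $\varepsilon \sim N(0, \sigma^2)$ on the proximity scale. Centering
  uses the factorial design means (4 for gain and loss; $33/7$ for
  conflict), so the generative weights coincide with the regression
  coefficients whenever clamping is inactive — the basis of all exact
  parameter-recovery tests. Noise is applied before clamping, keeping
  the generative model conjugate to the fitted linear model except at
  the boundaries.
* **Expected value** (`act_expected_value`): expected coin change at
  proximity $x$ is $(x/100) \cdot 0.5 \cdot (g - l)$, linear in $x$, so
  the maximizer sits at 100 when $g > l$ and at 0 when $g < l$. The tie
  $g = l$ is resolved to 50, the scale's start position, so indifference
  injects no directional bias.
* **Prospect** (`act_prospect`): $v = 0.5(g^{\alpha} - \lambda
  l^{\alpha})$ with loss aversion $\lambda \ge 1$ and curvature
  $\alpha \in (0, 1]$; proximity is $50 + s \cdot v$ plus noise. With
  $\lambda = \alpha = 1$ it reduces to an EV-proportional policy.

Reaction times are lognormal (log-mean `rt_log_mean`, default
`log(1500)` ms; log-SD 0.4), truncated to $[1, 10000]$ ms, mixed with an
explicit ceiling probability `rt_ceil_prob` that models failing to
choose within the 10 s deliberation window. The task literature
specifies no RT mechanism; this mixture exists so the RT-based exclusion
rules are exercisable. A ceiling trial is recorded at the start-position
proximity 50 and is excluded by the trial filter downstream, so its
recorded proximity never enters an index.

## The index-extraction pipeline

1. **Filtering** (`filter_trials`): trials with RT < 150 ms
   (anticipatory) and RT at the 10,000 ms ceiling (no choice) are
   removed; the report decomposes the input count exactly and the filter
   is idempotent.
2. **Design** (`build_design`): centered gain, loss, conflict, their
   three pairwise products (recentered), and centered RT, plus an
   intercept. The phrase "interaction terms" among the three magnitude
   predictors is implemented as the pairwise set without the three-way
   term — the minimal reading — switchable via `interactions =
   "three_way"` or `"none"`. Centering is within subject over retained
   trials. Zero-variance columns (e.g. constant RT) are dropped with a
   warning; the condition number is reported.
3. **Per-subject OLS** (`fit_subject`): classical unbiased
   residual-variance estimator, two-sided t tests, plus standardized
   coefficients (slope × SD(x)/SD(y)). Zero response variance or a
   singular design sets `degenerate` and zero coefficients with
   undefined inference. Whether RT belongs in the per-subject model or
   only the group model is ambiguous in the source description; the
   default includes it in both, toggleable via `include_rt`.
4. **QC** (`qc_subject`): per study variant — online sessions are
   excluded when ≥ 80% of input trials hit the RT ceiling; pediatric
   sessions when fewer than 49 retained trials remain or neither
   $\beta_{Gain}$ nor $\beta_{Loss}$ is significant at two-sided 0.05;
   in-lab adult sessions apply no extra rule.
5. **Group model** (`fit_group_model`): one linear mixed-effects model of
   trial-level proximity on the same fixed effects plus age and a single
   centered binary sex contrast, random intercept per participant, REML
   via `nlme::lme` with containment degrees of freedom (reported
   alongside every test so other df conventions can be compared). Fixed
   effects are centered at the grand mean across retained trials. If
   estimation fails — e.g. zero residual variance from deterministic
   agents — the model refits as pooled OLS with a `fallback_ols` flag.
6. **Reliability** (`icc3k`): consistency-type, average-of-k-fixed-raters
   ICC(3,k) with k = runs, from the two-way ANOVA decomposition; it
   satisfies $ICC = 1 - 1/F$ identically, which the tests verify against
   an `aov()` oracle. Rows with missing run-wise coefficients are removed
   listwise because the decomposition assumes a complete layout. A zero
   error mean square yields ICC 1 with infinite F.
7. **Associations** (`correlate`): a variable whose adjusted
   Fisher–Pearson skewness exceeds 1 in absolute value is
   log-transformed with a shift making its minimum 1
   ($x \to \log(x - \min x + 1)$, defined for nonpositive inputs) and
   then winsorized at the 5th/95th percentiles; variables within the
   threshold enter untouched. The order is fixed:
   skew-check → log → winsorize. One conditioning pass that brings
   |skew| ≤ 1 is a fixed point of the procedure; a pass that does not
   (possible for extreme shapes, since the shifted log is weaker than a
   plain log) would transform again — a property of the printed rule
   itself. Partial correlations residualize both conditioned variables
   on the covariates and use the t transform with $n - 2 - k$ degrees of
   freedom. No multiple-testing correction is applied by default,
   matching the original reporting.
8. **Loss bias** (`bias_statistic`): the four post-task 0–10 ratings are
   compared against objective outcomes mapped to the same scale —
   frequencies × 10; gained/lost coin totals min–max scaled within
   session (the magnitude anchors "few"/"many" are relative, so an
   absolute mapping would be arbitrary; equal totals map to the
   midpoint). The bias is the difference of differences, zero for a
   calibrated reporter; no published formula exists for this statistic,
   so scale-matched calibration-zero construction is the package's
   design choice.

## The synthetic cohort generator

`cohort_spec()` + `generate_cohort()` emulate the four study designs
(`study_template("study1")` … `"study4"`): sample sizes 20/37/120/51,
run counts 3/2/3/3, the online variant's $10 base + $0.10/coin payment
and a 30% noncompliant subgroup that mostly hits the deliberation
ceiling (mirroring the observed 36/120 exclusion rate), and the
pediatric ANX/HV split obtained by thresholding the SCARED-like score at
the quantile giving the published 27/24 group sizes.

Population defaults, chosen once as plausible for this task: intercept
$N(50, 10^2)$, $w_g \sim N(5, 2^2)$, $w_l \sim N(-5, 2^2)$, $w_c \sim
N(0, 2^2)$ (conflict sensitivity varies in sign across subjects, as
observed), trial noise SD $N(12, 3^2)$ truncated at 0 — giving
per-subject $R^2 \approx 0.6$ and near-universally significant gain and
loss coefficients, as reported for the adult samples. Symptom scores are
integer, range-clipped affine maps of latent standard normals; a planted
coupling $\rho$ shares the target parameter's latent normal with weight
$\rho$ (Gaussian copula), which controls the population Pearson
correlation without committing to any clinical model. Template coupling
values (e.g. STAI–$w_g$ of −0.45 in the replication-style template) are
testing conventions, not estimates. Subjective reports inflate the
loss-side ratings by $1 + \kappa_{loss}$ (default 0.5, which robustly
reproduces the loss-overestimation pattern) plus bounded uniform noise.

What the generator does **not** emulate: learning or fatigue across
trials, RT–choice coupling, item-level questionnaire structure,
non-Gaussian trait distributions, and any dependence of policy noise on
trial content. Passing recovery tests therefore show that the pipeline
is correct and well calibrated under its own generative assumptions —
not that human data satisfy those assumptions.

A consequence worth knowing when planning power analyses with the
generator: a planted trait–parameter correlation is attenuated in the
fitted indices by trial-level noise (for the defaults, the correlation
between fitted $\beta_{Gain}$ over 98 trials and true $w_g$ is about
0.9), by proximity clamping (~2.5% of trials at the defaults), and by
integer rounding of scale scores. A planted $\rho = -0.45$ thus surfaces
as roughly $-0.42$ in fitted coefficients, and detection power at
$n = 37$ is near 0.7–0.75 rather than the ~0.8 an unattenuated
correlation would give.

## Numerical choices and degenerate inputs

* Design singularity is detected by QR rank; coefficient covariances use
  the Cholesky inverse of $X^\top X$; recovery oracles in the test suite
  solve the normal equations independently and agree to < 1e−8 relative
  error.
* Simulation sizes in the shipped tests: 1,000 replicate sessions for CI
  coverage, 200 replicate cohorts for power-style checks, 500 random
  matrices for the ICC identity, 10,000 draws for binomial rate checks —
  each sized so Monte-Carlo error is small relative to the tolerance it
  guards.
* Empty retained-trial sets, all-ceiling sessions, zero-variance
  responses, no-door-opened sessions, and zero-variance bias vectors are
  all explicit, flagged paths rather than errors mid-pipeline.
* Seeds: every simulation entry point takes a seed and derives
  per-subject sub-seeds within 32-bit range; cohorts, sessions and
  pipeline outputs are pure functions of (spec, seed).

## Limitations

The simulator is a desk-scale instrument for validating the
index-extraction machinery, power planning, and regression testing of
analysis code. It deliberately omits presentation-level features
(animation, audio, joystick dynamics) and makes no claim that its agent
families span human strategy space; published group-level coefficient
magnitudes from human samples depend on scaling conventions not fully
specified in the source description and are not targets of this package.
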