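# doorsim

Simulation and psychometric analysis of the **Doors** approach-avoidance
conflict task.

## The problem

Approach-avoidance conflicts — situations where a single action carries
both potential reward and potential harm — are central to motivated
behavior, and their maladaptive resolution (notably excessive *passive
avoidance*: forgoing rewards because loss is also possible) is a hallmark
of anxiety. The Doors task quantifies these tendencies: each trial offers
a potential gain of $g \in \{1,\dots,7\}$ coins against a potential loss
of $l \in \{1,\dots,7\}$ coins, and the participant chooses a proximity
$x \in [0,100]$ to the door. Proximity maps linearly onto the probability
the door opens, $p = x/100$; an opened door pays $+g$ or $-l$ with equal
probability. One run crosses all 49 $(g,l)$ cells once, in random order.

Per-subject OLS regression of proximity on the mean-centered magnitudes
yields the behavioral indices

- $\beta_{Gain}$ — gain approach (lower values = passive avoidance),
- $\beta_{Loss}$ — active loss avoidance,
- $\beta_{Conflict}$ — sensitivity to conflict $c = 7 - |g - l|$,

alongside their interactions and reaction time as covariates. The package
implements the full environment, parameterized behavioral agents (linear,
expected-value, prospect-theory), synthetic cohorts with copula-planted
symptom-parameter correlations, trial filtering and subject QC,
mixed-effects group inference (`nlme`), run-wise ICC(3,k) test-retest
reliability ($ICC = 1 - 1/F$), symptom/performance association analyses
with skew-conditional log-winsorize conditioning, and subjective
loss-bias statistics — so the entire index-extraction pipeline can be
stress-tested by parameter recovery on agents with known ground truth.

This package simulates and analyzes; it does not present stimuli to
humans and consumes no human datasets.

## Worked example

```r
library(doorsim)

# an agent with known ground truth: w_gain = 5, w_loss = -5, w_conflict = -1
agent <- agent_params(w_gain = 5, w_loss = -5, w_conflict = -1, noise_sd = 10)
sess  <- simulate_session(agent, session_config(n_runs = 3), seed = 11)
fit_subject(sess$records)
#> Subject s01: n=147 trials, R^2=0.739
#>              term  estimate std_estimate      se      t         p
#> 1     (Intercept) 49.359733       0.0000 0.74086 66.625 2.29e-107
#> 2            gain  3.988917       0.4665 0.56358  7.078  6.61e-11
#> 3            loss -4.405343      -0.5152 0.56498 -7.797  1.35e-12
#> 4        conflict -1.020829      -0.0994 0.86645 -1.178  2.41e-01
#> ...
```

The fitted `gain` and `loss` coefficients recover the generating weights
(5 and −5) within their standard errors; at `noise_sd = 0` recovery is
exact to machine precision.

A full replication-style cohort (37 subjects, two 49-trial runs, trait
anxiety coupled to the gain weight), end to end:

```r
res <- run_pipeline(list(template = "study2", seed = 42))
res
#> doorsim pipeline summary
#> ========================
#> Subjects: 37 analyzed of 37 after QC
#> beta_gain: mean 4.976 (SD 1.960)
#> beta_loss: mean -4.812 (SD 1.982)
#> beta_conflict: mean -0.263 (SD 2.451)
#> ICC(3,2) beta_gain = 0.73, F(36,36) = 3.64, p = 9.74e-05
#> ICC(3,2) beta_loss = 0.79, F(36,36) = 4.67, p = 5.64e-06
#> ICC(3,2) beta_conflict = 0.43, F(36,36) = 1.77, p = 0.0459
#> frequency_bias: mean 2.41, t(36) = 22.55, p = 7.9e-23
#> magnitude_bias: mean 0.27, t(36) = 2.92, p = 0.00607
```

Reading the output: mean $\beta_{Gain}$ and $\beta_{Loss}$ match the
generative population means (±5 proximity units per coin); the ICC rows
give cross-run reliability of each index with its F test; the bias rows
are one-sample t tests of the loss-bias scores — positive and
significant here because the template's reporters inflate loss-side
ratings by 50%. `run_pipeline(..., out_dir = "out")` additionally writes
every table (coefficients, QC decisions, group mixed model, reliability,
run comparisons, associations, performance, bias) as CSV plus a
checksummed `manifest.json`.

A thin CLI wrapper over the same functions ships at `inst/cli/doors.R`
(`Rscript doors.R all --template study2 --out out --seed 42`).

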