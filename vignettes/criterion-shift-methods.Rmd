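---
title: "Models and design machinery for feedback-induced criterion shifts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design machinery for feedback-induced criterion shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(criterionshift)
```

## What this package models

An old/new recognition experiment in which participants first study 40
scene images, then complete two 40-trial recognition tests (20 old + 20 new
each). Between the tests, participants assigned to a *commission* condition
receive feedback insinuating that they falsely recognize new material, and
participants in an *omission* condition that they fail to recognize old
material; a control group gets none. The scientific question is whether such
feedback shifts the signal-detection response criterion c — stricter after
commission feedback, more liberal after omission feedback — and whether that
shift is mediated by momentary ("state") memory distrust.

The package provides four layers: signal-detection arithmetic
(`sdt_indices()` and friends), the preregistered design analysis
(`power_design()`, `simulate_minimal_effect_power()`,
`simulate_equivalence_power()`, `derive_sesoi()`), a full synthetic-data
generator (`sim_config()`, `simulate_experiment()`), and the inference
pipeline (`run_pipeline()` and its parts).

## Signal-detection layer

All indices assume equal-variance Gaussian signal detection. Observed rates
of 0 or 1 have no normal quantile, so a correction policy is explicit
everywhere: the default `half_count` replaces 0 with 1/(2N) and 1 with
1 − 1/(2N) (the most common convention in the recognition literature);
`log_linear` adds 0.5 to every cell; `none` refuses degenerate rates. The
choice matters only for near-ceiling responders; published analyses seldom
state their correction, so results on real data can differ marginally by
policy — which is why it is a visible argument rather than a constant.

The identity β = exp(c·d′) holds algebraically and is enforced to 1e−10 in
the tests. Normal quantiles come from R's `qnorm`, which is accurate to
well below 1e−9.

## The SESOI and the design analysis

The smallest effect size of interest is defined behaviorally, not
statistically: the top 25% of participants "most receptive" to the
manipulation make one more (or one fewer) hit *and* false-alarm response.
`derive_sesoi()` applies exactly that shift to a baseline cohort of counts
and summarizes the induced per-participant change in c. Because
receptiveness at baseline is unobservable, the receptive subset is chosen
uniformly at random (seeded). On a homogeneous 15/20-hit, 5/20-FA cohort the
shifted participants move by Δc = −0.159 and the cohort mean by ≈ −0.040;
on heterogeneous cohorts matched to typical recognition performance the
mean lands near 0.06 with an SD near 0.30, i.e. a standardized SESOI of
d = 0.2.

Power for the minimal-effect rule (CI lower bound above the SESOI) and the
equivalence rule (CI strictly inside symmetric bounds) is estimated by
Monte Carlo: two groups of normal deviates, a Welch t-interval at the 80%
level (TOST α = 0.1), 10,000 replicates by default. Three numerical
decisions worth recording:

- **Welch, not pooled, t-intervals.** The downstream pairwise analyses
  report fractional degrees of freedom, so the simulation uses the same
  interval; at n ≥ 100 per group the difference from a z-interval is far
  below Monte-Carlo error, which is what makes the closed-form oracle
  `analytic_power_oracle()` (a pure normal approximation) a valid
  independent cross-check at 3-MC-SE tolerance.
- **Strict containment** for equivalence: both CI endpoints strictly inside
  (−b, b). With continuous data the boundary event has probability zero;
  strictness only pins down the implementation.
- **10,000 default replicates**, giving an MC SE of ≈ 0.5 percentage points
  near 50% power — below reporting precision. Each run takes well under a
  second, so there is no accuracy/runtime trade-off worth exposing.

At the design point (true Δc = 0.15, σ = 0.30, SESOI 0.06) the package
reproduces ≈ 80% power at n = 100 per group and ≈ 96% at n = 210; under a
zero true effect with bounds ±0.06 at n = 210 the equivalence probability
is ≈ 56% by simulation and 55.7% in closed form. The corresponding figure
reported from a 1,000-replicate analysis was 54%, within its own ≈ 1.6-point
Monte-Carlo error of the analytic value.

## The synthetic-data generator

`simulate_experiment()` emulates the *structure* of the experiment, not any
particular dataset. Its defaults are the study conditions: 210 participants
per condition; latent d′ ~ N(1.4, 0.5²) and baseline c ~ N(0.16, 0.46²)
(the control-group descriptives); test-2 criterion shifts of +0.24
(commission) and −0.31 (omission), the observed condition-mean differences;
a 20% false-feedback probability; state-distrust effects of +0.55 on the
matching 10-point item over baselines of 3.96 / 4.52 with latent SD 2.2;
trait factors correlated 0.46 with item loadings tuned to Cronbach's α
≈ 0.95; a calibration-effort rating of mean 4.48, SD 1.76.

Generative choices where the design leaves the model open:

- **Latent response model.** Strength is N(d′, 1) for old items, N(0, 1)
  for new; the participant answers "old" when strength exceeds
  `latent_c + d′/2`. Placing the criterion relative to the distribution
  midpoint makes the standard estimator of c unbiased for `latent_c`, so
  parameter recovery is a meaningful test rather than a calibration
  exercise.
- **Ratings.** The 8-point recollection and belief scales are graded
  thresholds: 7 cut points equally spaced across the strength midpoint
  ±2.5 SD, applied to strength plus N(0, `rating_noise_sd`²) noise. Belief
  additionally receives a metacognitive calibration shift proportional to
  the participant's standardized omission-minus-commission distrust
  difference: higher commission distrust lowers belief, higher omission
  distrust raises it, matching the observed direction of the
  recollection-conditioned associations.
- **Receptiveness.** The condition shift is scaled by a LogNormal(−σ²/2, σ)
  multiplier with mean 1, so "the top 25% most receptive" is a well-defined
  subpopulation.
- **Bounded scales.** State-distrust ratings are generated on a continuous
  latent scale, then rounded and clipped to 1–10. Additivity is assumed on
  the latent scale; whether real feedback effects are additive before or
  after censoring is not identifiable from published summaries.
- **Stimulus heterogeneity** (`item_effect_sd`) defaults to 0. Nonzero
  values add per-item memorability effects — needed for non-degenerate
  stimulus random intercepts in mixed models — but attenuate the mapping
  from latent to recovered SDT parameters (probit regression dilution by
  1/√(1+σ²)), so the default keeps the recovery contract exact and tests
  switch heterogeneity on explicitly.
- **What is not modeled:** image content, encoding-phase timing, attrition
  between sessions, and the summary-feedback screen (represented only by
  the within-condition top-10% accuracy flag, ranked on test 2).

Passing tests on this generator show that the pipeline recovers what the
generator put in — unbiased criterion estimates, the condition ordering,
variance components. They do not show that real recognition data satisfy
equal-variance SDT, nor that real feedback effects are homogeneous
multiplicative shifts; conclusions about real data still require the real
data.

## The inference pipeline

`run_pipeline()` chains: union-of-rules exclusions → per-participant SDT
indices → manipulation-check ANOVAs, Welch-TOST equivalence tests and
dominance percentages → criterion ANOVAs (c and β) with pairwise
minimal-effect decisions → distrust→criterion regressions (90% CIs for the
SESOI comparison) → optional crossed random-intercept mixed models of
recollection, belief and recognition on condition.

Decision rules and their defaults (all `pipeline_config()` keys): TOST
α = 0.1, hence 80% CIs; equivalence bounds at Cohen's d = 0.2 × the pooled
(root-mean-square) SD for criterion contrasts and d = 0.8 for distrust
contrasts, computed from the data at hand as in the original decision
table; the three-way rule *minimal effect supported* (CI lower bound above
the SESOI) / *equivalent* (CI inside the bounds) / *suspend judgement*
(partial overlap).

Further analysis choices that were genuinely open:

- **η² confidence intervals** by inverting the noncentral-F CDF in the
  noncentrality parameter at 95%, the standard fixed-effects construction;
  the lower bound is clamped at 0 when the central F already exceeds the
  upper quantile.
- **Binary recognition models** default to a logistic link: reported
  intercepts near −7.6 with recollection coefficients near 1.9 are only
  plausible on the logit scale. A linear-probability option
  (`recognition_family = "gaussian"`) exists for variance-decomposition
  comparability with the continuous outcomes. The logit residual variance
  for ICC and pseudo-R² purposes is π²/3.
- **Pseudo-R²** is the variance-partition kind: marginal =
  fixed-effect variance over total, conditional adds the random-intercept
  variances. `glmer` fits use `nAGQ = 0` (adaptive quadrature off): with
  50,000 trials and crossed intercepts the Laplace refinement changes
  coefficients by far less than their SEs and triples the runtime.
- **Pairwise follow-ups** are Welch t-based throughout; no multiple-testing
  correction is applied anywhere, matching the analysis plan the package
  implements.
- **Standardized coefficients** are obtained by z-scoring outcome and
  numeric predictors before fitting (`standardize = TRUE`), not by
  post-hoc rescaling.

## Problem sizes and determinism

The test suite runs the generator at 40–210 participants per condition,
recovery checks on 10⁵ pooled trials, and power simulations at 3,000–10,000
replicates; the whole suite completes in well under a minute and the
acceptance script in about a second. Every stochastic entry point takes an
explicit seed; `simulate_experiment()` derives per-stage sub-seeds from the
master seed so that stages are independently reproducible, and identical
configurations produce byte-identical CSV output.

## Known limitations

Equal-variance SDT only (no unequal-variance or ROC extensions, by design);
Likert outcomes are modeled with Gaussian mixed models rather than ordinal
ones; the generator's feedback effect acts directly on the latent criterion
rather than through an explicit distrust mechanism, so mediation analyses
on synthetic data will correctly find *no* mediation; per-group sample
sizes after exclusions are random, so degrees of freedom in any published
analysis cannot be matched exactly.
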