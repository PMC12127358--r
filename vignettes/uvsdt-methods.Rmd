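---
title: "Signal-detection profiling of treatment decisions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal-detection profiling of treatment decisions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvsdt)
```

## The decision model

The package models a binary treatment decision (take up a treatment, or
decline it) as a threshold — a *criterion* — on a continuous *decision
driver*, under unequal-variance signal detection theory. Two drivers and
decisions are built in:

* **SEDEP** (starting a sound enrichment device evaluation period,
  i.e. audiological care), driven by hearing loss at 8 kHz on the
  worse-functioning ear, in dB HL on the axis [0, 130];
* **PCU** (psychosocial counseling uptake), driven by the baseline Tinnitus
  Handicap Inventory (THI) score on [0, 100].

Participants belong to one of two latent *truth states*: treatment success
(`T+`, an improvement of strictly more than 7 THI points from baseline to
post-treatment — the questionnaire's minimal clinically important
difference) or non-success (`T−`, anything else; an improvement of exactly
7 points counts as `T−`). Within each truth state the driver is assumed
logistically distributed with state-specific location `mu` and scale `s`
(standard deviation `s·pi/sqrt(3)`). The logistic family is used throughout
because its CDF is the inverse logit, which makes the ROC analysis below
exact rather than approximate, and each distribution equivalently carries
the `(−mu/s, 1/s)` intercept/slope parameterization of its logit-linear CDF.

A *positive decision corresponds to the driver exceeding the criterion*:
more hearing loss makes audiological care more likely, a higher THI burden
makes counseling more likely. This orientation makes the true-positive
probability the upper tail of the `T+` distribution.

### Accuracy: the double-logit ROC

For a criterion $c$, $P_{TP}(c) = 1 - F_+(c)$ and $P_{FP}(c) = 1 - F_-(c)$.
Because the logistic survival function satisfies
$\mathrm{logit}(1 - F(c)) = (\mu - c)/s$, the two logits are *exactly*
affine in each other:

$$\mathrm{logit}\,P_{TP} \;=\; \frac{s^-}{s^+}\,\mathrm{logit}\,P_{FP}
\;+\; \frac{\mu^+ - \mu^-}{s^+}.$$

`roc_accuracy()` reports this slope (`roc_slope`, the truth-state scale
ratio) and intercept (`roc_intercept`, the separability of the truth states
in units of the `T+` scale). Intercept 0 with slope 1 is chance
performance. The affinity is a closed-form identity, and the test suite
verifies it to 1e−9 over randomized models.

### Utility: likelihood-ratio criteria

`likelihood_ratio()` computes $\mathcal{L}(x) = f_+(x)/f_-(x)$. A criterion
placed where $\mathcal{L} > 1$ is *strict*, where $\mathcal{L} < 1$
*lenient*, and the *unbiased* criterion is the root of
$\mathcal{L}(x) = 1$. The expected-value-optimal criterion solves
$\mathcal{L}(c) = \beta$ with

$$\beta = \frac{P(T^-)}{P(T^+)}\cdot
\frac{B(T^-\&D^-) + C(T^-\&D^+)}{B(T^+\&D^+) + C(T^+\&D^-)},$$

so with equal priors and equal costs/benefits the optimal and unbiased
criteria coincide. Two conventions exist for whether $\mathcal{L}$ should
also carry the prior odds; since $\beta$ multiplies the prior odds
explicitly, folding them into $\mathcal{L}$ as well would double-count
them. The package therefore defaults to the pure density ratio
(`mode = "density_ratio"`) and exposes `mode = "posterior_odds"` for the
alternative reading; every output records which mode produced it.

**Numerical choices.** Probabilities are clamped to
$[10^{-12}, 1-10^{-12}]$ before the logit so curves stay finite at extreme
criteria. Roots of $\mathcal{L}(x) = \beta$ are found by scanning the
criterion grid (512 evenly spaced points spanning the driver axis) for sign
changes of $\log \mathcal{L} - \log\beta$ and refining each bracket with
`uniroot` to $|\mathcal{L}-\beta| < 10^{-6}$; in unequal-variance models
$\mathcal{L}$ is non-monotone and can cross a level twice (all roots are
returned, flagged) or never (an explicit error reporting the attainable
range). Grid points where $f_-$ underflows are flagged and excluded from
summaries rather than propagated as astronomically large ratios.

## Fitting

`fit_logistic()` maximizes the logistic log-likelihood over `(mu, log s)`
with BFGS and the analytic gradient, started from the sample median and the
method-of-moments scale. Groups with fewer than 5 distinct values, or zero
spread, are refused rather than fitted. The test suite checks the optimizer
against an exhaustive grid search of the log-likelihood (step 0.01) and
against an independent fitter.

A Bayesian variant (`method = "bayes_grid"`) computes the posterior on a
bounded grid in the `(−mu/s, 1/s)` parameterization under weakly
informative priors — normal(0, 10²) on the intercept and half-normal(10) on
the slope — and reports marginal posterior medians. These priors are the
package's own choice of weakly informative defaults; maximum likelihood is
the default method because it is deterministic and assumption-light.

`uvsdt()` applies this per truth state after labelling records by the
7-point rule; records without a post-treatment THI score are labelled
`undefined`, excluded from fitting and counted (no imputation is attempted;
a user with externally imputed scores can simply fill `thi_post` before
fitting). Records missing a *decision* still contribute to the truth-state
distributions, since the model fits drivers per truth state, not per
decision. The prior $P(T^+)$ defaults to the labelled-state fraction and
can be overridden.

## Resampling inference

`make_loo_datasets()` builds the exhaustive leave-one-out collection: $n$
datasets of size $n-1$, each participant absent from exactly one, ordered
by participant id. `make_random_partitions()` draws complementary splits
(by default 72 vs the remaining participants, 100 repetitions), with each
repetition seeded as `seed + r` so runs are bit-reproducible.
`fit_all()` refits the model on every dataset, recording `roc_slope`,
`roc_intercept` and the likelihood-ratio curve on a shared grid; datasets
that fall below 5 records in a truth state are skipped with the reason
logged.

Summaries follow the fence-screening convention: values more than 1.5 IQR
outside the quartiles are removed (quartiles by linear interpolation
between order statistics, `stats::quantile` type 7 — one convention,
declared and tested), then the median and 2.5/97.5 percentiles of the
retained values are reported together with dataset and outlier counts. The
screen is applied to the per-dataset scalar parameters and pointwise to the
likelihood-ratio values across datasets; grid points flagged in a majority
of datasets are masked. A parameter's null value (0 for the intercept,
1 for the slope) is rejected at the two-sided 5% level when it falls
outside the percentile interval; two groups are declared different when
their intervals are disjoint — the only rule expressible purely from the
interval limits, and a conservative one.

**A caveat the package surfaces rather than hides.** Leave-one-out
percentile intervals of a point estimator measure *single-deletion
sensitivity*, whose width shrinks like $1/n$ — not sampling variance. They
are therefore far narrower than bootstrap intervals and anti-conservative
as hypothesis tests: under an equal-truth generator the LOO interval
rarely covers the null. `profile_cohort(resampling = "bootstrap")` and
`bootstrap_estimates()` provide the conventional nonparametric bootstrap as
a sampling-variance companion, and the null-scenario test in the suite uses
it. The LOO mode remains the default profiling engine because it is the
exhaustive, deterministic construction the analysis is built around.

## The synthetic cohort generator

No participant-level clinical dataset ships with the package, so
`simulate_cohort()` generates cohorts with exactly the structure the model
assumes, plus known ground truth for every downstream test: truth states
drawn from the group prior; drivers drawn from the truth-state logistic
distributions truncated to their axes (via the inverse-CDF map, equivalent
to resample-until-in-range — clipping would pile mass at the bounds and
corrupt the fits); decisions from the criterion indicator flipped with a
noise probability; and THI improvements drawn uniformly from integer
ranges on the correct side of the 7-point threshold ([8, 40] for `T+`,
[−10, 7] for `T−` — the least structured choice respecting the boundary),
so relabelling the generated cohort recovers the generating truth states
wherever the post score is observed.

Defaults echo the scale of a realistic tinnitus referral cohort: 143
participants, sex split 81/62, age split 58/85 at 55 years, laterality
69/74, prior success probability 71/143, hearing-loss truth states
logistic(65, 15)/(55, 15) (overall mean ≈ 61 dB HL, SD ≈ 27), THI truth
states logistic(45, 15)/(40, 15) (overall median ≈ 42), criteria at 60 dB
HL and 42 THI points, decision noise 0.1. Per-level overrides
(`group_by`/`groups`) support two-group scenarios such as a strict male
vs lenient female criterion; these are demonstration scenarios, not
reproductions of any clinical dataset.

What the generator does *not* emulate: item-level THI scoring, real
audiogram shapes, informative missingness, or any dependence of decisions
on unmodelled covariates. Passing recovery tests therefore show the
pipeline is self-consistent — they cannot show the logistic assumption
holds in real cohorts.

Two details deserve flagging. First, *axis truncation*: with scale 15 the
[0, 130] axis cuts ~1.3% of each hearing-loss tail, and because logistic
tails are heavy this biases fitted scales by several percent;
`truncation_bias_report()` quantifies the distortion and flags
configurations with more than 1% of mass outside the axis. Recovery tests
accordingly use a negligible-truncation truth (locations 75/55, scale 8,
tail mass ~1e−3). Second, `T+` baselines for the PCU pairing are drawn
above the minimum realisable improvement (8 points), a small extra
truncation reported by the same tool; tight recovery checks use the SEDEP
pairing, whose driver is real-valued and unrounded.

## Problem sizes and the recovery protocol

The recovery analysis runs single-group cohorts of 400, 1000 and 4000
participants (200, 500 and 2000 per truth state) across a fixed three-seed
sequence, with the exhaustive leave-one-out refit at every size. The
fitted `(mu, s)` are required to land within 2% of truth in the
median over the seed sequence at the largest size; the leave-one-out
medians of `roc_slope` and `roc_intercept` within 5% per seed; and the
seed-averaged combined error must decrease monotonically across the three
sizes. Percentile bands use 512-point criterion grids throughout.

## Known limitations

* The logistic truth-state family is assumed, not tested; no
  goodness-of-fit machinery is included.
* The between-group rule (interval disjointness) is conservative; a
  difference-distribution test would be sharper but needs the per-dataset
  estimates, which `compare_groups()` deliberately does not require so it
  can also run on published interval limits.
* The six hypothesis tests per analysis are reported independently without
  multiplicity correction, matching the analysis design the package
  mirrors.
* Bayesian fitting is a bounded-grid approximation with the package's own
  priors; it is exposed for sensitivity analysis, not as a reproduction of
  any external sampler.
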