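---
title: "Prevention modelling of MLTCs with role limitation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prevention modelling of MLTCs with role limitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mltcprev)
```

## The question and the estimand

Early-life adversity — low birthweight, maternal smoking, behavioural
difficulties, socioeconomic disadvantage — predicts multimorbidity in
midlife. `mltcprev` quantifies how much of the burden of *multiple
long-term conditions (MLTCs) with role limitation* could plausibly be
removed by real, evaluated early-life interventions, combining three
estimation layers:

1. adjusted odds ratios of the outcome on per-domain adversity scores;
2. scenario-specific population attributable fractions (PAFs) by
   model-based standardization; and
3. a counterfactual simulation applying published intervention effects
   to the cohort and projecting absolute risk reductions.

The estimand of layer 3 is deliberately concrete: *of the cases in a
given adversity category, how many would no longer be cases had the
combined interventions been rolled out universally in their childhood?*

## Outcome construction

The outcome is a composite. A participant is a **case** when they report
two or more of 22 long-term conditions **and** role limitation due to a
physical or emotional problem; a **control** reports neither. The SF-36
role-limitation subscales are scored as the mean of the items actually
answered (4 physical, 3 emotional, each 0/1 with 0 = limited); the flag
is "limited" when that mean equals 0 and missing only when every item
is missing. Participants carrying only one component of the composite
(role limitation without MLTCs, or MLTCs without role limitation) are
excluded so the control group is free of partial phenotypes; their
counts are logged by `select_analytical_sample()`. With partially
missing condition flags, MLTC status is resolved whenever the observed
flags already determine it, and left missing otherwise.

## Step 1 — adversity scores

Each raw variable is reduced to a 0/1 adversity indicator:

* a validated cutoff where one exists — birthweight < 2500 g (the WHO
  low-birthweight convention; the package treats the number as a
  parameter of the rule, never an implicit constant), and a high-risk
  threshold for the behaviour-screening score;
* otherwise the **bottom-decile rule**: adversity when the value lies
  strictly below the empirical 10th percentile of the cohort.

Two numerical choices matter and are fixed explicitly, because different
percentile dialects change flag counts: the percentile is type-7
(linear interpolation), and the comparison is *strictly below*, so ties
at the cutoff are not adverse and a constant variable yields no
adversity. Indicators are summed within each of the five domains and
capped into 0 / 1 / 2 / 3+ (very high scores are too rare to model
separately). Indicators are weighted equally within a domain; no
variable is privileged.

For variables named only as binary reports in the synthetic default
(e.g. teenage pregnancy, high parity), a real dataset can instead
declare threshold rules — maternal age < 20 years at delivery, parity
≥ 3 — through `rule_threshold_below()` / `rule_threshold_above()`; the
derivation machinery is rule-driven throughout.

## Missing data

Multiple imputation by chained equations, authored in-package:
initialize missing cells from the observed marginals, then sweep the
incomplete variables (least missing first) for `cycles` iterations,
drawing each from its conditional model given all other variables with
posterior-perturbed parameters — the standard Bayesian draws for linear
models (scaled inverse-chi-squared variance, normal coefficients), a
normal approximation around the IRLS estimate for logistic models,
linear-on-codes-then-round for ordinal covariates, and a log-scale
linear model for income. Predictive-mean matching is not implemented;
the round-to-level treatment of ordinals is coarse and is a documented
limitation. A conditional fit that fails to converge (separation in a
sparse cell) falls back to a ridge-stabilized fit and the event is
logged.

The study convention is M = 50 imputed datasets ("fifty imputation
cycles" in the source analysis's terminology, which we read as the
number of imputations, the standard reading; the within-chain sweep
count is unstated and defaults to 10). The outcome enters every
conditional model as a predictor, but imputed outcome values are never
analysed: rows whose outcome was originally missing are deleted from
all M copies after imputation (`drop_imputed_outcomes()`), a
multiple-imputation-then-deletion design. Observed cells are preserved
bit-exactly across copies, and the whole run is reproducible from its
seed.

All pooling uses Rubin's rules on the estimation scale (log-odds, log
PUF — never on the OR/PAF scale): T = W + (1 + 1/M)B with the Rubin
degrees of freedom for the t reference, collapsing to a normal
reference when the M estimates are identical.

## Step 2 — nested models

Three nested logistic specifications, each fitted per completed dataset
and pooled: Model 1, one fit per domain (that domain's score dummies,
coded against reference 0, plus sex and ethnicity); Model 2, all five
domains jointly plus sex and ethnicity; Model 3, Model 2 plus eleven
adult factors at age 46. Ordered adult factors (exercise days,
TV/internet hours, deprivation decile, financial difficulty, education,
occupational class, alcohol-use class) enter as single linear-in-code
terms by default — the source analysis lists their levels but not their
coding, and linear-in-code keeps reduced-size fits stable — with a
`adult_coding = "dummy"` switch for full indicator sets. Weekly income
is log-transformed and standardized. Ethnicity is binary in the
synthetic default (the emulated 1970 cohort has little ethnic
diversity); a real dataset with more levels would extend the design
builder.

The estimator is iteratively reweighted least squares with
step-halving, run to a relative log-likelihood change below 1e-10
(at most 100 iterations), Wald covariance from the inverse observed
information, and explicit detection of separation (a coefficient
diverging past |β| > 15) — reported on the fit object rather than
silently returned. Confidence intervals are Wald, significance is a
95% interval excluding 1, and no multiplicity adjustment is applied,
matching the per-cell convention of the source analysis. An empty score
category in a completed dataset is collapsed out of the design with a
logged warning.

## Step 3 — scenario PAFs

For each domain still significant in Model 3 (any score category's
interval excluding 1), six reduction scenarios are evaluated: 3+→2,
3+→1, 3+→0, 2→1, 2→0, 1→0. The estimator is model-based
standardization restricted to the scenario's exposed group: among
participants observed at the "from" category, average the fitted
probabilities at their actual covariates (p̄f), then with the domain's
score dummies switched to the "to" category and everything else fixed
(p̄c). PUF = p̄c/p̄f, PAF = 1 − PUF. This mirrors the behaviour of the
standard `punaf`-style postestimation (reference population = the
regression's analytical sample, restricted to the exposed group, as in
the "amongst cohort members with an adversity score of …" phrasing),
replicated in behaviour rather than algebra.

Whether the original intervals were analytic or resampled is not
stated in the source analysis, so both are offered: a seeded
nonparametric bootstrap (200 resamples, percentile, refitting the model
per resample) as the user-facing default, and a delta-method interval
on log PUF through the Wald covariance. Bootstrap resampling happens
within each imputed dataset and the resulting log-PUF variances are
then Rubin-pooled — one defensible ordering among several, chosen for
simplicity. Pooled intervals are back-transformed to the PAF scale.

## Steps 4–5 — intervention library and projection

The library (`table4_intervention_library()`) encodes eleven published
effect estimates from three UK programmes — Family Nurse Partnership,
Family Hubs, Teenage Pregnancy Prevention Framework. Two effect kinds
exist: an additive shift in natural units (+324 g birthweight, applied
to everyone, with the adversity indicator re-derived against the cutoff
*frozen at first derivation*, so a percentile rule keeps its original
cutoff), and fractional reclassification (a random sample of the
at-risk group — those with the adverse indicator — set to non-adverse;
the sampled count is `f · n` rounded half away from zero, so a fraction
too small to move half a person moves nobody, with a log note). No
intervention targets maternal age at delivery or parity. Effects are
variable-disjoint and applied with independent sub-seeds, so library
order cannot change the result (asserted at run time); effects are
assumed additive across interventions, as in the source framework, and
uptake/selection processes are out of scope.

After application, domain scores are recomputed from the modified
indicators (`recompute_scores()` — deliberately *not* a re-binarization,
which would undo reclassifications), transitions among cases are
tabulated per domain, and each significant scenario PAF is applied to
its movers. Movers are counted once, on the first completed analysis
dataset: the alternative — recounting per imputed dataset and averaging
— is equally defensible but produces fractional movers, and the
projection layer is meant to talk about whole people.

**Dual rounding conventions.** The projection reports both
`paf × movers` kept fractional (ARR = 100·paf·movers/cases) and rounded
to the nearest whole person first (ARR = 100·round(paf·movers)/cases).
The worked examples this projection style comes from mix the two
conventions (13.0% of 53 movers is announced as seven people and 2.5%
of 272, the fractional convention; 20.0% of 42 movers is announced as
nine people and 11.5% of 78, consistent only with the integer
convention applied to a larger underlying count). Because neither
convention reproduces all printed numbers alone, both are first-class
outputs, labelled, and neither is silently preferred. The two ARRs
always bracket each other within 100/cases percentage points.

## The synthetic cohort generator

The generator emulates the *data structure* the pipeline needs, with
known ground truth:

* **Size and composition.** Default 8580 participants pre-exclusion
  (echoing the emulated cohort's outcome denominators), five domains
  with 5/8/4/4/4 variables.
* **Dependence.** One standard-normal latent factor per domain with
  loading 0.5 on every member variable — without it, multi-adversity
  (3+) cells would be far too rare. Domains are mutually independent;
  real domains correlate, which is a stated limitation.
* **Raw measurements.** Birthweight ~ Normal(3350 g, 500 g) clamped at
  500 g with the 2500 g rule; six developmental raw scores ~ standard
  normal for the bottom-decile rule (the behaviour-screen score uses a
  high-tail cutoff at 1.28 SD, a stand-in for its validated cutoff,
  whose numeric value is not printed in the source); all other
  indicators generated directly as binary with marginal prevalences in
  [0.05, 0.30] (the source states no marginals; these are placeholders
  on the realistic side, chosen once).
* **Outcome.** Each participant's case propensity is plogis(η) with η
  the declared linear predictor over capped domain scores, sex, and
  adult covariates. Non-cases are split into controls and the two
  excluded groups at fixed rates (4.13% role-limitation-only and 26.22%
  MLTC-without-limitation among non-cases, the rates implied by the
  emulated denominators); condition flags and SF-36 items are then
  constructed to be *exactly consistent* with the drawn group, with
  condition counts weighted by published marginal prevalences. Because
  group exclusion is independent of covariates given non-case status,
  the analytical-sample logit keeps the generating slopes and shifts
  only the intercept — which is what makes parameter-recovery testing
  exact. The default intercept (−3.93) is calibrated so the
  analytical-sample case prevalence is ≈ 0.119.
* **Mediation.** Adult covariates depend on total capped adversity with
  a log-odds shift of 0.3 per score point and carry their own outcome
  coefficients, so the Model-1 → Model-3 attenuation pattern is real in
  the generator, not an artifact.
* **Missingness.** Missing-at-random by construction: each variable's
  missingness logit depends only on always-observed drivers (sex, and
  one domain indicator that is exempted from missingness), with the
  intercept solved numerically so the expected rate hits the target
  exactly. Default rates — 5% on birth variables, 10% on age-10
  variables, 8% on adult covariates, small rates on outcome items — are
  the package's own choice; the source states none.

What passing tests on this generator do and do not show: they validate
the estimation machinery (score derivation, imputation coverage,
pooling, standardization, projection arithmetic) under known truth;
they do not validate the substantive published estimates, which depend
on licensed cohort data. Cohort-level outputs on synthetic runs (ORs,
PAFs) are properties of the synthetic conditions.

## Numerical choices and degenerate inputs

* IRLS tolerance 1e-10 relative log-likelihood, step-halving keeps the
  likelihood non-decreasing; ridge stabilization only inside imputation
  fallbacks, never in the analysis models.
* A degenerate PAF scenario (from = to) returns exactly 0 with a
  zero-width interval.
* `n_participants = 0` yields an empty table with the full schema;
  empty vectors are rejected by the binarizer; a 100%-missing variable
  is rejected by the imputer; an empty exposed group names its scenario
  in the error.
* Every stage draws from a named, independently derived seed stream
  (`derive_seed()`), so the four stage seeds recorded in a run manifest
  reproduce a run byte-for-byte; there is no reliance on global RNG
  state across stages.

## Problem sizes used in the test suite

The suite exercises the pipeline at reduced but statistically adequate
sizes, chosen as the package's own test design: calibration and
recovery checks at n = 20000 complete cohorts; null-calibration of PAF
intervals over 40 replicates of n = 4000 with M = 2; mediation
attenuation over 25 seeds of n = 3000; imputation coverage over 40
replicates of n = 1800 at 15% MCAR with M = 5; end-to-end determinism
at n = 1200 with M = 2. The acceptance script runs the full default
cohort (n = 8580) with M = 5 and delta intervals.

## Known limitations

* Domains are generated independently; real early-life domains
  correlate, so synthetic Model-2 adjustment effects are milder than in
  real data.
* Ordinal imputation by rounding a linear draw can distort sparse
  extreme categories.
* The bootstrap/imputation ordering (resample within imputation, then
  pool) is one defensible choice; nested alternatives exist.
* Intervention effects are additive, universally applied, and
  selection-free by design — the estimand is a policy illustration, not
  a forecast of programme uptake.
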