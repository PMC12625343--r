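# mltcprev

Prevention modelling of **multiple long-term conditions (MLTCs) with role
limitation** at midlife from early-life adversity.

Public-health teams increasingly want to know not just *whether* childhood
adversity predicts adult multimorbidity, but *how much of it real,
evaluated interventions could plausibly remove*. `mltcprev` implements a
five-step pipeline that answers that question for a birth-cohort design,
and ships a calibrated synthetic-cohort generator so every stage is
testable without access to licensed cohort data.

The five steps:

1. **Adversity scores.** Raw early-life variables in five domains
   (prenatal–birth; development and behaviour; education; socioeconomic;
   parental–family environment) are each reduced to a binary adversity
   indicator — by a validated cutoff where one exists (birthweight
   < 2500 g), otherwise by the bottom 10% of the cohort distribution —
   then summed within each domain and capped into the categories
   0 / 1 / 2 / 3+.
2. **Nested models.** The outcome is the composite *MLTCs with role
   limitation*: two or more of 22 self-reported long-term conditions
   **and** an SF-36 role-limitation flag (mean of answered items equal
   to 0). Participants with only one component are excluded so controls
   are clean. Logistic regressions (own IRLS implementation) are fitted
   at three adjustment levels — sex/ethnicity; plus the other domains;
   plus eleven adult factors at age 46 — across M datasets completed by
   chained-equations multiple imputation, pooling log-odds by Rubin's
   rules:  W = mean within-imputation variance, B = between-imputation
   variance, T = W + (1 + 1/M)·B.
3. **Scenario PAFs.** For domains still significant in the fully
   adjusted model, population attributable fractions for the six score
   reductions (3+→2, 3+→1, 3+→0, 2→1, 2→0, 1→0) are computed by
   model-based standardization (G-computation): among participants at
   the "from" score, PAF = 1 − p̄(counterfactual)/p̄(factual), with
   bootstrap or delta-method intervals on log(1 − PAF).
4. **Intervention library.** Eleven published effect estimates from the
   Family Nurse Partnership, Family Hubs, and the UK Teenage Pregnancy
   Prevention Framework (e.g. +324 g birthweight for everyone; 8% of
   smoking mothers reclassified; 62% of teenage pregnancies averted).
5. **Counterfactual projection.** The combined interventions are applied
   to the cohort, domain scores are recomputed, score-category
   transitions among cases are tabulated, and each significant PAF is
   applied to its movers to project absolute risk reductions (ARR) —
   under both a fractional and a whole-person rounding convention.

## Worked example

```r
library(mltcprev)

lv <- c("0", "1", "2", "3+")
# 272 cases with a prenatal-birth adversity score of 1; the combined
# interventions move 53 of them down to 0; the 1->0 scenario PAF is 13.0%
tt <- transition_table(factor(rep("1", 272), levels = lv),
                       factor(c(rep("0", 53), rep("1", 219)), levels = lv),
                       rep("case", 272), "prenatal")
project_reduction(tt, 0.130, scenario = paf_scenario_spec("prenatal", "1", "0"))
#> <scenario_result> prenatal 1 to 0
#>   movers 53 of 272 cases (19.5%); PAF 13.0%
#>   projected removals: 6.89 (fractional) / 7 (integer)
#>   absolute risk reduction: 2.5% (fractional) / 2.6% (integer)
```

Reading: 19.5% of the 272 affected cohort members achieve the score
reduction; applying the 13.0% attributable fraction, about 7 of those 53
movers would no longer report MLTCs with role limitation — an absolute
risk reduction of roughly 2.5% in that adversity group.

A full synthetic study runs end-to-end from one config:

```r
cfg <- run_config(mode = "synthetic", M = 5, ci_method = "delta",
                  seeds = list(cohort = 1, imputation = 2,
                               intervention = 3, bootstrap = 4),
                  output_dir = "run1")
res <- run_study(cfg)
res$manifest$case_prevalence   # ~0.119 on the calibrated default cohort
res$pafs                       # pooled scenario PAF grid
```

A thin command-line wrapper with per-stage subcommands
(`run`, `synth`, `derive`, `impute`, `model`, `paf`, `simulate`,
`validate`) lives at `inst/cli/mltcprev.R`.

## Scope notes

The synthetic generator emulates the *structure* of a 1970s British
birth cohort (sample size, five correlated adversity domains, adult
mediators, outcome prevalence near 11.9% of the analytical sample,
missing-at-random missingness); it does not emulate the real cohort's
sampling design, attrition, or measurement instruments, so cohort-level
estimates (odds ratios, PAFs) are properties of the synthetic
conditions, not re-estimates of any published value. See the methods
vignette (`vignettes/prevention-modelling.Rmd`) for the model, its
assumptions, and all numerical choices.
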