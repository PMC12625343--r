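# Shared fixtures: all built in code, scaled for fast test runs.

# alias derived_score_<d> columns to the score_<d> names the generating
# outcome model uses, so the generator's design can be refitted
add_score_aliases <- function(tab, spec) {
  for (d in spec$domain_specs) {
    tab[[paste0("score_", d$name)]] <- tab[[paste0("derived_score_", d$name)]]
  }
  tab
}

# spec with every outcome effect switched off and a fixed case propensity;
# missingness off so imputation degenerates to copies
null_effect_spec <- function(n, prevalence = 0.119) {
  spec <- default_bcs70_spec(n_participants = n)
  spec$outcome_coefficients[] <- 0
  spec$outcome_coefficients[["(Intercept)"]] <- stats::qlogis(prevalence)
  spec$missingness$rates[] <- 0
  spec
}

# spec with a strong development-domain effect routed partly through
# adult mediators (large adversity-to-covariate shifts and large
# covariate-to-outcome coefficients)
mediation_spec <- function(n) {
  spec <- default_bcs70_spec(n_participants = n)
  spec$missingness$rates[] <- 0
  spec$outcome_coefficients[["score_development"]] <- 0.45
  spec$outcome_coefficients[["smoker"]] <- 0.9
  spec$outcome_coefficients[["financial_difficulty"]] <- 0.35
  spec$outcome_coefficients[["exercise_days"]] <- -0.15
  for (i in seq_along(spec$adult_covariate_specs)) {
    spec$adult_covariate_specs[[i]]$shift <-
      if (spec$adult_covariate_specs[[i]]$type == "lognormal") 0.15 else 0.6
  }
  spec
}

# complete generated cohort taken through derivation and score aliasing
derived_complete_cohort <- function(spec, seed) {
  tab <- generate_cohort(spec, seed = seed)
  tab <- derive_outcome(tab)
  tab <- derive_scores(tab, spec$domain_specs)
  tab
}

# generate -> (optional missingness) -> analytical sample -> impute ->
# drop imputed outcomes -> derived score tables
analysis_tables <- function(spec, seed, M = 2L, cycles = 5L, miss = TRUE) {
  tab <- generate_cohort(spec, seed = seed)
  if (miss) tab <- inject_missingness(tab, spec, seed = seed)
  an <- select_analytical_sample(derive_outcome(tab))
  raw <- unlist(lapply(spec$domain_specs, function(d) names(d$variables)))
  adult <- vapply(spec$adult_covariate_specs, `[[`, "", "name")
  cols <- c("sex_female", "ethnicity_nonwhite", raw, adult, "derived_case")
  imp <- impute_chained(an, variable_models = c(weekly_income = "lognormal"),
                        M = M, cycles = cycles,
                        seed = derive_seed(seed, "imp"), columns = cols)
  imp <- drop_imputed_outcomes(imp, "derived_case")
  lapply(imp$tables, derive_scores, domain_specs = spec$domain_specs)
}

detect_domains_of <- function(tab) {
  sub("^derived_score_(.*)_cat$", "\\1",
      grep("^derived_score_.*_cat$", names(tab), value = TRUE))
}

# 50-row deterministic fixture table with derived scores for PAF checks:
# one domain driving the outcome, hand-rolled without the generator
small_paf_fixture <- function(seed = 401L, n = 50L) {
  spec <- default_bcs70_spec(n_participants = n)
  spec$missingness$rates[] <- 0
  derived_complete_cohort(spec, seed)
}
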