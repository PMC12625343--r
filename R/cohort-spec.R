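#' Declare a domain of early-life adversity variables
#'
#' A domain groups conceptually related early-life variables (e.g. all
#' prenatal-to-birth circumstances). Each member variable carries an
#' adversity rule that reduces it to a 0/1 indicator, plus — for the
#' synthetic generator — a description of how to simulate its raw values.
#'
#' @param name domain label (snake_case, unique within a cohort spec).
#' @param variables named list; one entry per variable, each a list with
#'   `rule` (an [adversity_rules] object) and `gen` (a generation spec from
#'   [gen_binary()] or [gen_normal()]).
#' @return a `domain_spec` object.
#' @export
domain_spec <- function(name, variables) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is.null(names(variables)) || any(!nzchar(names(variables)))) {
    stop("domain_spec: `variables` must be a fully named list")
  }
  if (anyDuplicated(names(variables))) {
    stop("domain_spec: duplicate variable names within domain '", name, "'")
  }
  for (v in names(variables)) {
    entry <- variables[[v]]
    if (!inherits(entry$rule, "adversity_rule")) {
      stop("domain_spec: variable '", v, "' lacks a valid adversity rule")
    }
  }
  structure(list(name = name, variables = variables), class = "domain_spec")
}

#' Synthetic generation specs for raw variables
#'
#' `gen_binary` simulates a 0/1 adversity report with a target marginal
#' prevalence; `gen_normal` simulates a continuous measurement as a
#' Gaussian mixed with the domain's shared latent factor. `adverse = "low"`
#' puts the adverse tail at small values (e.g. birthweight, motor scores),
#' `"high"` at large values (e.g. a behaviour-difficulties scale).
#'
#' @param prevalence target marginal prevalence of the adversity report.
#' @param mean,sd marginal mean and standard deviation in natural units.
#' @param adverse which tail is adverse: `"low"` or `"high"`.
#' @param floor optional hard lower bound (values are clamped).
#' @name gen_specs
NULL

#' @rdname gen_specs
#' @export
gen_binary <- function(prevalence) {
  stopifnot(prevalence > 0, prevalence < 1)
  list(kind = "binary", prevalence = prevalence)
}

#' @rdname gen_specs
#' @export
gen_normal <- function(mean = 0, sd = 1, adverse = c("low", "high"),
                       floor = NULL) {
  adverse <- match.arg(adverse)
  list(kind = "normal", mean = mean, sd = sd, adverse = adverse, floor = floor)
}

adult_covariate <- function(name, type, base, direction, shift = 0.3,
                            levels = NULL) {
  list(name = name, type = type, base = base, direction = direction,
       shift = shift, levels = levels)
}

#' Build a cohort specification
#'
#' Bundles everything the synthetic generator needs: sample size, the five
#' domain declarations, the logistic outcome model (named log-odds
#' coefficients over generated or derived columns, plus `"(Intercept)"`),
#' adult covariate marginals with their dependence on total adversity,
#' missingness targets and the missingness drivers, and the study-design
#' constants for the composite outcome.
#'
#' @param n_participants cohort size before outcome-group exclusions.
#' @param domain_specs list of [domain_spec()] objects (five by default).
#' @param outcome_coefficients named numeric vector of log-odds terms;
#'   names must resolve to generated columns, `score_<domain>` capped
#'   scores, or `log_income_z`.
#' @param adult_covariate_specs list of adult covariate declarations.
#' @param missingness list with `rates` (named per-column proportions in
#'   \[0,1\]), `sex_shift` and `indicator`/`indicator_shift` (the
#'   missing-at-random drivers; drivers themselves must stay observed).
#' @param outcome_structure study-design constants: exclusion-group rates
#'   among non-cases, long-term-condition marginal prevalences, the
#'   limitation-type split and item-response probabilities.
#' @param seed default master seed for [generate_cohort()].
#' @return a `cohort_spec` object.
#' @seealso [default_bcs70_spec()] for the calibrated default.
#' @export
cohort_spec <- function(n_participants, domain_specs, outcome_coefficients,
                        adult_covariate_specs, missingness, outcome_structure,
                        seed = 1L) {
  spec <- structure(
    list(n_participants = n_participants,
         domain_specs = domain_specs,
         outcome_coefficients = outcome_coefficients,
         adult_covariate_specs = adult_covariate_specs,
         missingness = missingness,
         outcome_structure = outcome_structure,
         seed = seed),
    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' Validate a cohort specification
#'
#' Checks structural invariants: unique variable names across domains,
#' fully parameterized rules, missingness rates in \[0,1\] naming known
#' columns and sparing the MAR driver columns, and outcome coefficients
#' that resolve to generated or derived columns.
#'
#' @param spec a `cohort_spec`.
#' @return the spec, invisibly; stops with the offending field otherwise.
#' @export
validate_cohort_spec <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("not a cohort_spec")
  n <- spec$n_participants
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0 || n != floor(n)) {
    stop("invalid cohort_spec field `n_participants`: must be a non-negative integer")
  }
  all_vars <- unlist(lapply(spec$domain_specs, function(d) names(d$variables)))
  if (anyDuplicated(all_vars)) {
    stop("invalid cohort_spec field `domain_specs`: variable name(s) repeated across domains: ",
         paste(unique(all_vars[duplicated(all_vars)]), collapse = ", "))
  }
  dn <- vapply(spec$domain_specs, `[[`, "", "name")
  if (anyDuplicated(dn)) stop("invalid cohort_spec field `domain_specs`: duplicate domain names")

  rates <- spec$missingness$rates
  if (length(rates)) {
    if (is.null(names(rates)) || any(!nzchar(names(rates)))) {
      stop("invalid cohort_spec field `missingness`: rates must be named")
    }
    if (any(is.na(rates) | rates < 0 | rates > 1)) {
      stop("invalid cohort_spec field `missingness`: rates must lie in [0, 1]")
    }
    known <- spec_column_names(spec)
    unknown <- setdiff(names(rates), known)
    if (length(unknown)) {
      stop("invalid cohort_spec field `missingness`: rate(s) for unknown column(s): ",
           paste(unknown, collapse = ", "))
    }
    drivers <- c("sex_female", spec$missingness$indicator)
    hit <- intersect(names(rates)[rates > 0], drivers)
    if (length(hit)) {
      stop("invalid cohort_spec field `missingness`: driver column(s) must stay observed: ",
           paste(hit, collapse = ", "))
    }
  }

  cf <- spec$outcome_coefficients
  if (is.null(names(cf)) || !"(Intercept)" %in% names(cf)) {
    stop("invalid cohort_spec field `outcome_coefficients`: named vector with \"(Intercept)\" required")
  }
  resolvable <- c("(Intercept)", spec_column_names(spec),
                  paste0("score_", dn), "log_income_z")
  unknown <- setdiff(names(cf), resolvable)
  if (length(unknown)) {
    stop("invalid cohort_spec field `outcome_coefficients`: name(s) do not resolve to a generated column: ",
         paste(unknown, collapse = ", "))
  }

  ex <- spec$outcome_structure$exclusion_rates
  if (any(ex < 0) || sum(ex) >= 1) {
    stop("invalid cohort_spec field `outcome_structure`: exclusion rates must be non-negative and sum below 1")
  }
  invisible(spec)
}

# every raw column name the generator will emit for a spec
spec_column_names <- function(spec) {
  c("participant_id", "sex_female", "ethnicity_nonwhite",
    unlist(lapply(spec$domain_specs, function(d) names(d$variables)), use.names = FALSE),
    vapply(spec$adult_covariate_specs, `[[`, "", "name"),
    names(spec$outcome_structure$ltc_prevalence),
    paste0("sf36_phys_", 1:4), paste0("sf36_emo_", 1:3))
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> n =", x$n_participants, "\n")
  for (d in x$domain_specs) {
    cat("  domain", d$name, ":", length(d$variables), "variables\n")
  }
  cat("  adult covariates:", length(x$adult_covariate_specs),
      "| outcome terms:", length(x$outcome_coefficients) - 1L, "\n")
  invisible(x)
}

# names of the 22 long-term conditions with marginal prevalences used by
# the generator (self-reported conditions at midlife; hearing loss in one
# or both ears is a single condition)
default_ltc_prevalence <- function() {
  c(asthma = 0.117, diabetes = 0.038, cancer = 0.015,
    high_blood_pressure = 0.103, heart_problems = 0.029, eczema = 0.088,
    chronic_fatigue_syndrome = 0.015, stomach_bowel_gallbladder = 0.112,
    bladder_kidney = 0.034, liver_disease = 0.006, arthritis = 0.076,
    stroke = 0.006, depression = 0.239, anxiety = 0.186,
    hearing_loss = 0.041, epilepsy = 0.010, eye_blindness_low_vision = 0.004,
    eye_diabetes_disease = 0.003, eye_glaucoma = 0.005,
    endometriosis = 0.023, menieres_disease = 0.001, psoriasis = 0.024)
}

#' Default cohort specification emulating a 1970 British birth cohort
#'
#' Returns the calibrated default [cohort_spec()]: 8580 participants, five
#' adversity domains — prenatal/birth (5 variables, including continuous
#' birthweight ~ Normal(3350 g, 500 g) clamped at 500 g with the 2500 g
#' low-birthweight cutoff), development/behaviour (8 variables, six of
#' them continuous raw scores so the bottom-decile rule has something to
#' act on), education, socioeconomic and parental-family (4 variables
#' each) — with within-domain dependence through one standard-normal
#' latent factor per domain (loading 0.5), eleven adult covariates at age
#' 46 that depend mildly on total adversity (log-odds shift 0.3 per capped
#' score point) so they act as mediators, and a logistic outcome model
#' whose intercept is calibrated so the analytical-sample prevalence of
#' MLTCs with role limitation is approximately 0.119.
#'
#' @param n_participants cohort size; default 8580.
#' @param seed default master seed stored in the spec.
#' @return a `cohort_spec`.
#' @export
default_bcs70_spec <- function(n_participants = 8580L, seed = 1L) {
  prenatal <- domain_spec("prenatal", list(
    birthweight = list(rule = rule_threshold_below(2500, "g"),
                       gen = gen_normal(3350, 500, adverse = "low", floor = 500)),
    smoked_in_pregnancy = list(rule = rule_binary(), gen = gen_binary(0.28)),
    teen_pregnancy      = list(rule = rule_binary(), gen = gen_binary(0.08)),
    mother_age_under20  = list(rule = rule_binary(), gen = gen_binary(0.10)),
    parity_3plus        = list(rule = rule_binary(), gen = gen_binary(0.12))))

  development <- domain_spec("development", list(
    rutter_behaviour = list(rule = rule_threshold_above(1.28, "sd"),
                            gen = gen_normal(0, 1, adverse = "high")),
    steps_walking_backwards = list(rule = rule_bottom_decile(),
                                   gen = gen_normal(0, 1, adverse = "low")),
    child_behavioural_problems = list(rule = rule_binary(), gen = gen_binary(0.15)),
    child_hand_control = list(rule = rule_bottom_decile(),
                              gen = gen_normal(0, 1, adverse = "low")),
    child_temper = list(rule = rule_binary(), gen = gen_binary(0.12)),
    child_clumsy_games = list(rule = rule_bottom_decile(),
                              gen = gen_normal(0, 1, adverse = "low")),
    balance_right_leg = list(rule = rule_bottom_decile(),
                             gen = gen_normal(0, 1, adverse = "low")),
    balance_left_leg = list(rule = rule_bottom_decile(),
                            gen = gen_normal(0, 1, adverse = "low"))))

  education <- domain_spec("education", list(
    low_reading_score       = list(rule = rule_binary(), gen = gen_binary(0.12)),
    low_maths_score         = list(rule = rule_binary(), gen = gen_binary(0.12)),
    special_education_need  = list(rule = rule_binary(), gen = gen_binary(0.08)),
    frequent_school_absence = list(rule = rule_binary(), gen = gen_binary(0.10))))

  socioeconomic <- domain_spec("socioeconomic", list(
    social_housing        = list(rule = rule_binary(), gen = gen_binary(0.20)),
    free_school_meals     = list(rule = rule_binary(), gen = gen_binary(0.18)),
    overcrowded_household = list(rule = rule_binary(), gen = gen_binary(0.15)),
    low_family_income     = list(rule = rule_binary(), gen = gen_binary(0.15))))

  parental_family <- domain_spec("parental_family", list(
    single_parent_household = list(rule = rule_binary(), gen = gen_binary(0.10)),
    parental_divorce        = list(rule = rule_binary(), gen = gen_binary(0.08)),
    low_parental_interest   = list(rule = rule_binary(), gen = gen_binary(0.12)),
    family_tension          = list(rule = rule_binary(), gen = gen_binary(0.10))))

  adult <- list(
    adult_covariate("exercise_days", "ordinal",
                    c(0.18, 0.12, 0.14, 0.14, 0.12, 0.10, 0.08, 0.12),
                    direction = -1, levels = 0:7),
    adult_covariate("education_level", "ordinal",
                    c(0.18, 0.30, 0.14, 0.12, 0.18, 0.08),
                    direction = -1, levels = 0:5),
    adult_covariate("nssec", "ordinal",
                    c(0.10, 0.18, 0.12, 0.12, 0.14, 0.12, 0.12, 0.10),
                    direction = +1, levels = 1:8),
    adult_covariate("weekly_income", "lognormal",
                    c(meanlog = log(500), sdlog = 0.5),
                    direction = -1, shift = 0.08),
    adult_covariate("smoker", "binary", 0.22, direction = +1),
    adult_covariate("tv_hours", "ordinal", c(0.10, 0.30, 0.30, 0.18, 0.12),
                    direction = +1, levels = 0:4),
    adult_covariate("internet_hours", "ordinal", c(0.25, 0.30, 0.22, 0.13, 0.10),
                    direction = +1, levels = 0:4),
    adult_covariate("partner", "binary", 0.75, direction = -1),
    adult_covariate("imd_decile", "ordinal", rep(0.1, 10),
                    direction = -1, levels = 1:10),
    adult_covariate("financial_difficulty", "ordinal",
                    c(0.30, 0.30, 0.25, 0.10, 0.05),
                    direction = +1, levels = 1:5),
    adult_covariate("audit_class", "ordinal", c(0.15, 0.65, 0.20),
                    direction = +1, levels = 0:2))

  coefs <- c(
    "(Intercept)" = -3.93,  # calibrated: analytical-sample prevalence ~ 0.119
    score_prenatal = 0.32, score_development = 0.38, score_education = 0.12,
    score_socioeconomic = 0.18, score_parental_family = 0.15,
    sex_female = 0.15, smoker = 0.35, exercise_days = -0.06,
    tv_hours = 0.06, financial_difficulty = 0.14, audit_class = 0.12,
    imd_decile = -0.03, education_level = -0.08, partner = -0.10,
    log_income_z = -0.08)

  age10_vars <- c(names(development$variables), names(education$variables),
                  names(socioeconomic$variables), names(parental_family$variables))
  age10_vars <- setdiff(age10_vars, "social_housing")  # MAR driver stays observed
  rates <- c(
    stats::setNames(rep(0.05, 4), c("birthweight", "smoked_in_pregnancy",
                                    "teen_pregnancy", "parity_3plus")),
    mother_age_under20 = 0.05,
    stats::setNames(rep(0.10, length(age10_vars)), age10_vars),
    stats::setNames(rep(0.08, 11),
                    vapply(adult, `[[`, "", "name")),
    stats::setNames(rep(0.002, 22), names(default_ltc_prevalence())),
    stats::setNames(rep(0.03, 7), c(paste0("sf36_phys_", 1:4),
                                    paste0("sf36_emo_", 1:3))))

  outcome_structure <- list(
    # among non-cases: role limitation without MLTCs, and MLTCs without
    # role limitation, are set aside from the analytical sample
    exclusion_rates = c(role_only = 0.0413, mltc_only = 0.2622),
    ltc_prevalence = default_ltc_prevalence(),
    ltc_extra_mean = 1.3,      # extra conditions beyond 2 for MLTC rows (Poisson)
    control_one_ltc_prob = 0.367,
    limited_split = c(phys_only = 0.32, emo_only = 0.37, both = 0.31),
    item_one_prob = 0.85)

  cohort_spec(
    n_participants = as.integer(n_participants),
    domain_specs = list(prenatal, development, education, socioeconomic,
                        parental_family),
    outcome_coefficients = coefs,
    adult_covariate_specs = adult,
    missingness = list(rates = rates, sex_shift = 0.5,
                       indicator = "social_housing", indicator_shift = 0.3),
    outcome_structure = outcome_structure,
    seed = as.integer(seed))
}

#' Serialize / restore a cohort spec as YAML
#'
#' @param spec a `cohort_spec`.
#' @param path file path.
#' @return `spec_to_yaml` returns `path` invisibly; `spec_from_yaml`
#'   returns the restored, validated `cohort_spec`.
#' @export
spec_to_yaml <- function(spec, path) {
  validate_cohort_spec(spec)
  ser <- unclass(spec)
  ser$domain_specs <- lapply(spec$domain_specs, function(d) {
    list(name = d$name, variables = lapply(d$variables, function(v) {
      list(rule = unclass(v$rule), gen = v$gen)
    }))
  })
  ser$adult_covariate_specs <- lapply(spec$adult_covariate_specs, function(a) {
    a$base <- as.list(a$base)
    a
  })
  ser$outcome_coefficients <- as.list(spec$outcome_coefficients)
  ser$missingness$rates <- as.list(spec$missingness$rates)
  ser$outcome_structure$ltc_prevalence <-
    as.list(spec$outcome_structure$ltc_prevalence)
  ser$outcome_structure$exclusion_rates <-
    as.list(spec$outcome_structure$exclusion_rates)
  ser$outcome_structure$limited_split <-
    as.list(spec$outcome_structure$limited_split)
  yaml::write_yaml(ser, path, precision = 15L)
  invisible(path)
}

#' @rdname spec_to_yaml
#' @export
spec_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  domains <- lapply(raw$domain_specs, function(d) {
    vars <- lapply(d$variables, function(v) {
      rule <- new_rule(v$rule$kind, v$rule$cutoff, v$rule$units)
      list(rule = rule, gen = v$gen)
    })
    domain_spec(d$name, vars)
  })
  os <- raw$outcome_structure
  os$ltc_prevalence <- unlist(os$ltc_prevalence)
  os$exclusion_rates <- unlist(os$exclusion_rates)
  os$limited_split <- unlist(os$limited_split)
  miss <- raw$missingness
  miss$rates <- unlist(miss$rates)
  adult <- lapply(raw$adult_covariate_specs, function(a) {
    a$base <- unlist(a$base)
    if (!is.null(a$levels)) a$levels <- as.integer(unlist(a$levels))
    a
  })
  cohort_spec(
    n_participants = as.integer(raw$n_participants),
    domain_specs = domains,
    outcome_coefficients = unlist(raw$outcome_coefficients),
    adult_covariate_specs = adult,
    missingness = miss,
    outcome_structure = os,
    seed = as.integer(raw$seed))
}
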