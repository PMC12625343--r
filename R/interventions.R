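#' Declare an intervention effect
#'
#' An effect is either an `additive_shift` on a raw continuous variable
#' (in its natural units; the adversity indicator is re-derived against
#' the frozen cutoff) or a `fraction_reclassified` that moves a random
#' sample of the at-risk participants (those with the adverse indicator)
#' to non-adverse. Reclassification only ever removes adversity.
#'
#' @param target_variable name of the raw variable the effect touches.
#' @param effect_kind `"additive_shift"` or `"fraction_reclassified"`.
#' @param magnitude shift in natural units, or a fraction in \[0, 1\].
#' @param eligibility `"all"` (shift everyone) or `"adverse"` (only
#'   participants whose derived indicator is 1 are at risk).
#' @param source label of the originating programme.
#' @param units units of an additive shift (documentation).
#' @return an `intervention_effect`.
#' @export
intervention_effect <- function(target_variable,
                                effect_kind = c("additive_shift",
                                                "fraction_reclassified"),
                                magnitude, eligibility = c("adverse", "all"),
                                source = "", units = "") {
  effect_kind <- match.arg(effect_kind)
  eligibility <- match.arg(eligibility)
  if (effect_kind == "fraction_reclassified" &&
      (magnitude < 0 || magnitude > 1)) {
    stop("intervention_effect: fraction must lie in [0, 1]")
  }
  structure(list(target_variable = target_variable, effect_kind = effect_kind,
                 magnitude = magnitude, eligibility = eligibility,
                 source = source, units = units),
            class = "intervention_effect")
}

#' The built-in library of early-life intervention effects
#'
#' Eleven effects from published evaluations of three programmes — the
#' Family Nurse Partnership (FNP), Family Hubs, and the UK Teenage
#' Pregnancy Prevention Framework — mapped onto the variables of the
#' prenatal-birth and development-behaviour domains:
#'
#' * birthweight: +324 g for every cohort member (FNP);
#' * smoking in pregnancy: 8% of smokers reclassified (FNP);
#' * teenage pregnancy: 62% reclassified (Teenage Pregnancy Prevention
#'   Framework);
#' * high-risk behaviour-scale score: 39% reclassified (FNP);
#' * behavioural problems: 55% reclassified (FNP);
#' * temper: 2.6% reclassified (FNP);
#' * the five developmental markers (walking backwards, hand control,
#'   clumsiness, balance right/left): 6% reclassified each (Family Hubs).
#'
#' No effect exists for mother's age at delivery or parity — no
#' intervention targets them.
#'
#' @return list of 11 [intervention_effect()]s.
#' @export
intervention_library <- function() {
  fnp <- "Family Nurse Partnership"
  hubs <- "Family Hubs"
  tppf <- "Teenage Pregnancy Prevention Framework"
  list(
    intervention_effect("birthweight", "additive_shift", 324,
                        eligibility = "all", source = fnp, units = "g"),
    intervention_effect("smoked_in_pregnancy", "fraction_reclassified", 0.08,
                        source = fnp),
    intervention_effect("teen_pregnancy", "fraction_reclassified", 0.62,
                        source = tppf),
    intervention_effect("rutter_behaviour", "fraction_reclassified", 0.39,
                        source = fnp),
    intervention_effect("steps_walking_backwards", "fraction_reclassified",
                        0.06, source = hubs),
    intervention_effect("child_behavioural_problems", "fraction_reclassified",
                        0.55, source = fnp),
    intervention_effect("child_hand_control", "fraction_reclassified", 0.06,
                        source = hubs),
    intervention_effect("child_temper", "fraction_reclassified", 0.026,
                        source = fnp),
    intervention_effect("child_clumsy_games", "fraction_reclassified", 0.06,
                        source = hubs),
    intervention_effect("balance_right_leg", "fraction_reclassified", 0.06,
                        source = hubs),
    intervention_effect("balance_left_leg", "fraction_reclassified", 0.06,
                        source = hubs))
}

#' Apply one intervention effect to a derived cohort
#'
#' `additive_shift` adds the magnitude to every eligible raw value and
#' re-derives the adversity indicator against the cutoff frozen at first
#' derivation (so a cohort-percentile rule keeps its original cutoff).
#' `fraction_reclassified` samples `round(f * n_at_risk)` at-risk
#' participants without replacement (half-away-from-zero rounding;
#' seeded) and sets their indicator to non-adverse. All other cells are
#' untouched. When `f * n_at_risk < 0.5` nobody changes and the event is
#' noted as a message.
#'
#' @param cohort a table carrying the raw variable, its
#'   `derived_<variable>` indicator and the `"cutoffs"` attribute from
#'   [derive_scores()].
#' @param effect an [intervention_effect()].
#' @param seed integer seed for the sampling stream.
#' @param domain_specs the domain declarations (supplies the adversity
#'   rule for re-derivation after a shift).
#' @return the modified cohort table.
#' @export
apply_effect <- function(cohort, effect, seed = 1L, domain_specs = NULL) {
  v <- effect$target_variable
  ind_col <- paste0("derived_", v)
  if (!v %in% names(cohort)) stop("apply_effect: unknown variable ", v)
  if (!ind_col %in% names(cohort)) {
    stop("apply_effect: missing derived indicator for ", v,
         "; run derive_scores() first")
  }
  if (effect$effect_kind == "additive_shift") {
    rows <- if (effect$eligibility == "adverse") {
      which(cohort[[ind_col]] == 1)
    } else {
      seq_len(nrow(cohort))
    }
    cohort[[v]][rows] <- cohort[[v]][rows] + effect$magnitude
    rule <- find_rule(domain_specs, v)
    cuts <- attr(cohort, "cutoffs")
    cut <- if (!is.null(cuts) && v %in% names(cuts) && is.finite(cuts[[v]])) {
      cuts[[v]]
    } else {
      NULL
    }
    old <- cohort[[ind_col]]
    new <- binarize_adversity(cohort[[v]], rule, cutoff = cut)
    if (any(new > old, na.rm = TRUE)) {
      stop("apply_effect: shift would add adversity for ", v)
    }
    cohort[[ind_col]] <- new
  } else {
    at_risk <- which(cohort[[ind_col]] == 1)
    k <- as.integer(round_half_up(effect$magnitude * length(at_risk)))
    if (k == 0L) {
      message("apply_effect: ", v, ": fraction times at-risk count below 0.5; ",
              "no participant changed")
      return(cohort)
    }
    pick <- with_seed(derive_seed(seed, paste0("effect-", v)),
                      at_risk[sample.int(length(at_risk), k)])
    cohort[[ind_col]][pick] <- 0L
  }
  cohort
}

find_rule <- function(domain_specs, v) {
  if (is.null(domain_specs)) stop("apply_effect: domain_specs needed to re-derive ", v)
  for (d in domain_specs) {
    if (v %in% names(d$variables)) return(d$variables[[v]]$rule)
  }
  stop("apply_effect: no adversity rule found for ", v)
}

#' Apply the whole intervention library
#'
#' Effects are applied sequentially in library order, each drawing from
#' an independent sub-seed. The library is variable-disjoint (no two
#' effects touch the same variable — additivity across same-variable
#' effects is undefined and rejected), so application order cannot
#' change the result.
#'
#' @param cohort a derived cohort table.
#' @param effects list of [intervention_effect()]s (default: the
#'   built-in library).
#' @param seed integer master seed for the intervention stream.
#' @param domain_specs the domain declarations.
#' @return the modified cohort table.
#' @export
apply_all <- function(cohort, effects = intervention_library(),
                      seed = 1L, domain_specs = NULL) {
  targets <- vapply(effects, `[[`, "", "target_variable")
  if (anyDuplicated(targets)) {
    stop("apply_all: two effects target the same variable: ",
         paste(unique(targets[duplicated(targets)]), collapse = ", "))
  }
  for (e in effects) {
    cohort <- apply_effect(cohort, e, seed = seed, domain_specs = domain_specs)
  }
  cohort
}

#' Tabulate adversity-category transitions among cases
#'
#' Counts, among participants with the outcome (MLTCs with role
#' limitation), how many moved from each baseline score category to each
#' post-intervention category in one domain. Interventions only ever
#' remove adversity, so any participant whose category increased is an
#' error.
#'
#' @param scores_before,scores_after capped category vectors (factors or
#'   characters over `0,1,2,3+`) on the same participants.
#' @param groups outcome group labels (`"case"` rows are tabulated).
#' @param domain domain name (metadata).
#' @return a `transition_table`: `counts` (4x4 matrix from x to),
#'   `group_sizes` (baseline case counts per category), `domain`.
#' @export
transition_table <- function(scores_before, scores_after, groups, domain) {
  before <- factor(as.character(scores_before), levels = score_levels)
  after <- factor(as.character(scores_after), levels = score_levels)
  if (length(before) != length(after) || length(before) != length(groups)) {
    stop("transition_table: input length mismatch")
  }
  up <- !is.na(before) & !is.na(after) &
    match(after, score_levels) > match(before, score_levels)
  if (any(up)) {
    stop("transition_table: adversity score increased for ", sum(up),
         " participant(s); interventions must not add adversity")
  }
  cases <- groups %in% "case"
  counts <- unclass(table(from = before[cases], to = after[cases]))
  storage.mode(counts) <- "integer"
  structure(list(counts = counts,
                 group_sizes = as.integer(rowSums(counts)) |>
                   stats::setNames(rownames(counts)),
                 domain = domain),
            class = "transition_table")
}

#' @export
print.transition_table <- function(x, ...) {
  cat("<transition_table>", x$domain, "| cases:", sum(x$counts), "\n")
  print(x$counts)
  invisible(x)
}

#' Movers for a scenario
#'
#' @param transition a [transition_table()].
#' @param scenario a [paf_scenario_spec()].
#' @return integer count of cases moving from the scenario's `from`
#'   category to its `to` category.
#' @export
transition_movers <- function(transition, scenario) {
  transition$counts[scenario$from, scenario$to]
}

#' Percentage of a case group, to one decimal
#'
#' The reporting convention used throughout the projection outputs:
#' `100 * count / group`, rounded to one decimal place.
#'
#' @param count numerator (movers or projected removals).
#' @param group_cases denominator (baseline cases in the category).
#' @return numeric percentage rounded to one decimal.
#' @export
percent_of_group <- function(count, group_cases) {
  if (group_cases <= 0) stop("percent_of_group: empty group")
  round(100 * count / group_cases, 1)
}

#' Project the absolute reduction in outcome risk for one scenario
#'
#' Applies a scenario PAF to the cases who achieved that scenario's
#' score reduction (the movers), projecting how many would no longer
#' report the outcome, and expresses the projection as an absolute risk
#' reduction (ARR) among all baseline cases in the `from` category.
#'
#' Both rounding conventions are first-class outputs: the fractional
#' convention keeps `paf * movers` as a real count (ARR =
#' `100 * paf * movers / group_cases`); the integer convention rounds
#' the projected removals to the nearest whole person first (ARR =
#' `100 * round(paf * movers) / group_cases`). They bracket each other
#' within `100 / group_cases` percentage points and neither is silently
#' preferred.
#'
#' @param transition a [transition_table()] for the scenario's domain.
#' @param paf_estimate a `paf_estimate` (or a bare proportion) for the
#'   scenario.
#' @param group_cases baseline case count in the `from` category;
#'   defaults to the transition table's row total.
#' @param scenario the [paf_scenario_spec()]; defaults to the estimate's.
#' @return a `scenario_result`: `movers`, `paf`,
#'   `projected_removals_fractional`, `projected_removals_integer`,
#'   `arr_fractional_pct`, `arr_integer_pct` (percentages to one
#'   decimal).
#' @export
project_reduction <- function(transition, paf_estimate, group_cases = NULL,
                              scenario = NULL) {
  paf <- if (inherits(paf_estimate, "paf_estimate")) paf_estimate$paf else paf_estimate
  if (is.null(scenario) && inherits(paf_estimate, "paf_estimate")) {
    scenario <- paf_estimate$scenario
  }
  if (is.null(scenario)) stop("project_reduction: scenario required")
  movers <- transition_movers(transition, scenario)
  if (is.null(group_cases)) {
    group_cases <- unname(transition$group_sizes[scenario$from])
  }
  if (group_cases == 0) stop("project_reduction: no cases in group ",
                             scenario$from)
  frac <- paf * movers
  int <- as.integer(round_half_up(frac))
  structure(list(scenario = scenario, movers = as.integer(movers), paf = paf,
                 projected_removals_fractional = frac,
                 projected_removals_integer = int,
                 arr_fractional_pct = percent_of_group(frac, group_cases),
                 arr_integer_pct = percent_of_group(int, group_cases),
                 group_cases = as.integer(group_cases)),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result>", x$scenario$domain, scenario_label(x$scenario), "\n")
  cat(sprintf("  movers %d of %d cases (%.1f%%); PAF %.1f%%\n",
              x$movers, x$group_cases,
              percent_of_group(x$movers, x$group_cases), 100 * x$paf))
  cat(sprintf("  projected removals: %.2f (fractional) / %d (integer)\n",
              x$projected_removals_fractional, x$projected_removals_integer))
  cat(sprintf("  absolute risk reduction: %.1f%% (fractional) / %.1f%% (integer)\n",
              x$arr_fractional_pct, x$arr_integer_pct))
  invisible(x)
}

#' Render a narrative case-study report for a scenario
#'
#' Produces a short plain-text narrative, in the style of an
#' illustrative case study, with the scenario's numbers injected.
#'
#' @param result a `scenario_result`.
#' @param domain_label human-readable domain label.
#' @return a character scalar (multi-line).
#' @export
case_study_report <- function(result, domain_label = result$scenario$domain) {
  s <- result$scenario
  paste0(
    "CASE STUDY - ", domain_label, " domain\n",
    "Among the ", result$group_cases, " cohort members with a domain ",
    "adversity score of ", s$from, " who reported MLTCs with role ",
    "limitation, the combined interventions moved ", result$movers,
    " (", percent_of_group(result$movers, result$group_cases), "%) down to a ",
    "score of ", s$to, ".\n",
    "Applying the ", round(100 * result$paf, 1), "% attributable-fraction ",
    "reduction for this scenario, ", result$projected_removals_integer,
    " of those ", result$movers, " movers would no longer report MLTCs ",
    "with role limitation.\n",
    "This is an absolute risk reduction of ", result$arr_integer_pct,
    "% (integer convention; ", result$arr_fractional_pct,
    "% under the fractional convention) among all cases with a score of ",
    s$from, ".\n")
}
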