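# Intervention library, effect application, transitions, projections.

score_levels_fixture <- function() c("0", "1", "2", "3+")

test_that("the built-in library holds the eleven published effects", {
  lib <- intervention_library()
  expect_length(lib, 11L)
  targets <- vapply(lib, `[[`, "", "target_variable")
  bw <- lib[[which(targets == "birthweight")]]
  expect_identical(bw$effect_kind, "additive_shift")
  expect_identical(bw$magnitude, 324)
  expect_identical(bw$units, "g")
  expect_identical(bw$eligibility, "all")
  fr <- stats::setNames(vapply(lib, `[[`, 0, "magnitude"), targets)
  expect_identical(unname(fr[c("smoked_in_pregnancy", "teen_pregnancy",
                               "rutter_behaviour", "child_behavioural_problems",
                               "child_temper")]),
                   c(0.08, 0.62, 0.39, 0.55, 0.026))
  expect_identical(unname(fr[c("steps_walking_backwards", "child_hand_control",
                               "child_clumsy_games", "balance_right_leg",
                               "balance_left_leg")]), rep(0.06, 5))
  # no intervention exists for maternal age or parity
  expect_false(any(c("mother_age_under20", "parity_3plus") %in% targets))
})

make_derived <- function(n = 200L, seed = 90L) {
  spec <- default_bcs70_spec(n_participants = n)
  spec$missingness$rates[] <- 0
  derived_complete_cohort(spec, seed)
}

test_that("an additive birthweight shift re-derives the indicator at the frozen cutoff", {
  spec <- default_bcs70_spec(n_participants = 50L)
  tab <- make_derived(400L)
  tab$birthweight[1] <- 2300
  tab <- derive_scores(tab, spec$domain_specs)  # refresh indicators
  expect_identical(tab$derived_birthweight[1], 1L)
  eff <- intervention_library()[[1]]
  out <- apply_effect(tab, eff, seed = 1, domain_specs = spec$domain_specs)
  expect_identical(out$birthweight[1], 2624)
  expect_identical(out$derived_birthweight[1], 0L)  # 2624 >= 2500
  expect_identical(out$birthweight[-1], tab$birthweight[-1] + 324)
})

test_that("fractional reclassification samples the exact rounded count", {
  tab <- data.frame(smoked_in_pregnancy = c(rep(1, 100), rep(0, 40)))
  tab$derived_smoked_in_pregnancy <- tab$smoked_in_pregnancy
  eff <- intervention_effect("smoked_in_pregnancy", "fraction_reclassified", 0.08)
  out <- apply_effect(tab, eff, seed = 5)
  expect_identical(sum(tab$derived_smoked_in_pregnancy) -
                     sum(out$derived_smoked_in_pregnancy), 8)
  # reclassification never adds adversity, and non-adverse rows are untouched
  expect_true(all(out$derived_smoked_in_pregnancy <= tab$derived_smoked_in_pregnancy))
  # zero fraction is the identity
  z <- suppressMessages(
    apply_effect(tab, intervention_effect("smoked_in_pregnancy",
                                          "fraction_reclassified", 0),
                 seed = 5))
  expect_identical(z, tab)
  # a fraction too small to move half a person changes nobody, with a note
  small <- tab[1:4, , drop = FALSE]
  expect_message(
    s <- apply_effect(small, intervention_effect("smoked_in_pregnancy",
                                                 "fraction_reclassified", 0.08),
                      seed = 5),
    "below 0.5")
  expect_identical(s$derived_smoked_in_pregnancy, small$derived_smoked_in_pregnancy)
})

test_that("library application is order-invariant, deterministic, and anti-monotone", {
  spec <- default_bcs70_spec(n_participants = 600L)
  tab <- make_derived(600L, seed = 91L)
  lib <- intervention_library()
  a <- apply_all(tab, lib, seed = 7, domain_specs = spec$domain_specs)
  b <- apply_all(tab, rev(lib), seed = 7, domain_specs = spec$domain_specs)
  expect_identical(a, b)
  a2 <- apply_all(tab, lib, seed = 7, domain_specs = spec$domain_specs)
  expect_identical(a, a2)
  # no indicator ever increases
  ind_cols <- grep("^derived_(birthweight|smoked|teen|rutter|steps|child|balance)",
                   names(tab), value = TRUE)
  for (cc in ind_cols) expect_true(all(a[[cc]] <= tab[[cc]]))
  # raw sums never increase after recomputation
  before <- recompute_scores(tab, spec$domain_specs)
  after <- recompute_scores(a, spec$domain_specs)
  for (d in c("prenatal", "development")) {
    expect_true(all(after[[paste0("derived_score_", d)]] <=
                      before[[paste0("derived_score_", d)]]))
  }
  # same-variable duplicate effects are rejected
  expect_error(apply_all(tab, c(lib, lib[2]), seed = 1,
                         domain_specs = spec$domain_specs),
               "same variable")
  # empty effect list is the identity
  expect_identical(apply_all(tab, list(), seed = 1,
                             domain_specs = spec$domain_specs), tab)
})

test_that("transition tables count case moves and conserve totals", {
  # no intervention: diagonal
  sc <- factor(c("0", "1", "2", "3+", "1"), levels = c("0", "1", "2", "3+"))
  g <- c("case", "case", "case", "case", "control")
  tt <- transition_table(sc, sc, g, "prenatal")
  expect_identical(sum(diag(tt$counts)), 4L)
  expect_identical(sum(tt$counts), 4L)  # conservation: cases only
  # a known fixture cell
  before <- factor(rep("3+", 78), levels = c("0", "1", "2", "3+"))
  after <- factor(c(rep("2", 42), rep("3+", 36)), levels = c("0", "1", "2", "3+"))
  tt2 <- transition_table(before, after, rep("case", 78), "prenatal")
  expect_identical(tt2$counts["3+", "2"], 42L)
  expect_identical(unname(tt2$group_sizes["3+"]), 78L)
  # a single mover lands in exactly one cell
  tt3 <- transition_table(factor("3+", levels = score_levels_fixture()),
                          factor("0", levels = score_levels_fixture()),
                          "case", "prenatal")
  expect_identical(tt3$counts["3+", "0"], 1L)
  expect_identical(sum(tt3$counts), 1L)
  # score increases violate the intervention contract
  expect_error(transition_table(c("1"), c("2"), "case", "prenatal"), "increased")
})

test_that("projection applies the PAF under both rounding conventions", {
  before <- factor(rep("1", 272), levels = score_levels_fixture())
  after <- factor(c(rep("0", 53), rep("1", 219)), levels = score_levels_fixture())
  tt <- transition_table(before, after, rep("case", 272), "prenatal")
  res <- project_reduction(tt, 0.130, scenario = paf_scenario_spec("prenatal", "1", "0"))
  expect_identical(res$movers, 53L)
  expect_identical(res$projected_removals_integer, 7L)     # 6.89 rounds to 7
  expect_equal(res$projected_removals_fractional, 6.89)
  expect_identical(res$arr_fractional_pct, 2.5)
  expect_identical(res$arr_integer_pct, 2.6)
  expect_lte(res$projected_removals_integer, res$movers)
  # the two ARR conventions bracket each other within 100/group points
  expect_lte(abs(res$arr_integer_pct - res$arr_fractional_pct), 100 / 272)
  # zero PAF gives zero ARR under both conventions
  res0 <- project_reduction(tt, 0, scenario = paf_scenario_spec("prenatal", "1", "0"))
  expect_identical(res0$arr_fractional_pct, 0)
  expect_identical(res0$arr_integer_pct, 0)
  # empty case group errors
  expect_error(project_reduction(tt, 0.1,
                                 scenario = paf_scenario_spec("prenatal", "2", "0")),
               "no cases")
})

test_that("the case-study narrative carries the scenario numbers", {
  before <- factor(rep("3+", 78), levels = score_levels_fixture())
  after <- factor(c(rep("2", 42), rep("3+", 36)), levels = score_levels_fixture())
  tt <- transition_table(before, after, rep("case", 78), "prenatal")
  res <- project_reduction(tt, 0.20, scenario = paf_scenario_spec("prenatal", "3+", "2"))
  txt <- case_study_report(res, "prenatal-birth")
  expect_match(txt, "42")
  expect_match(txt, "78")
  expect_match(txt, "53.8")
})
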