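# Outcome derivation, adversity binarization, scores, analytical sample.

test_that("role limitation follows the mean-of-answered rule", {
  expect_true(derive_role_limitation(c(0, 0, 0, 0), 4L))
  expect_false(derive_role_limitation(c(1, 1, 1), 3L))
  # missing items are dropped from the mean, not counted as limitation-free
  expect_true(derive_role_limitation(c(0, 0, 0, NA), 4L))
  expect_false(derive_role_limitation(c(0, 1, 0, NA), 4L))
  expect_true(is.na(derive_role_limitation(c(NA, NA, NA), 3L)))
  expect_error(derive_role_limitation(c(0, 2, 0, 0), 4L), "non-binary")
  expect_error(derive_role_limitation(c(0, 0, 0), 4L), "expected 4")
})

test_that("outcome groups implement the case/control/exclusion partition", {
  flags <- function(k) c(rep(1, k), rep(0, 22 - k))
  expect_identical(derive_outcome_group(flags(3), TRUE, FALSE)$group, "case")
  expect_identical(derive_outcome_group(flags(1), FALSE, TRUE)$group,
                   "excluded_role_only")
  expect_identical(derive_outcome_group(flags(2), FALSE, FALSE)$group,
                   "excluded_mltc_only")
  expect_identical(derive_outcome_group(flags(0), FALSE, FALSE)$group, "control")
  # indeterminate MLTC status or limitation leaves the group missing
  expect_true(is.na(derive_outcome_group(c(1, NA, flags(0)[-(1:2)]), FALSE, FALSE)$group))
  expect_true(is.na(derive_outcome_group(flags(2), NA, FALSE)$group))
  # but missing flags that cannot change the verdict still resolve
  expect_identical(derive_outcome_group(c(1, 1, NA, rep(0, 19)), TRUE, FALSE)$group,
                   "case")
})

test_that("every labelled participant falls in exactly one group", {
  spec <- default_bcs70_spec(n_participants = 2000L)
  tab <- derive_outcome(generate_cohort(spec, seed = 31))
  g <- tab$derived_group
  expect_false(anyNA(g))
  expect_setequal(unique(g), c("case", "control", "excluded_role_only",
                               "excluded_mltc_only"))
  with(tab, {
    expect_true(all((derived_group == "case") ==
                      (derived_mltc & (derived_phys_limited | derived_emo_limited))))
    expect_true(all((derived_group == "control") ==
                      (!derived_mltc & !derived_phys_limited & !derived_emo_limited)))
  })
})

test_that("binarization handles thresholds, the bottom decile, and ties", {
  expect_identical(binarize_adversity(c(2300, 2501, 2500),
                                      rule_threshold_below(2500, "g")),
                   c(1L, 0L, 0L))
  # constant vector: nothing strictly below the percentile
  expect_identical(binarize_adversity(rep(7, 20), rule_bottom_decile()),
                   rep(0L, 20))
  # enumerated oracle: 1..100 flags exactly the bottom ten values
  flagged <- binarize_adversity(1:100, rule_bottom_decile())
  expect_identical(which(flagged == 1L), 1:10)
  expect_identical(sum(flagged), 10L)
  # missing in, missing out; empty input is an error
  expect_identical(binarize_adversity(c(1, NA, 3), rule_threshold_above(2)),
                   c(0L, NA, 1L))
  expect_error(binarize_adversity(numeric(0), rule_bottom_decile()), "empty")
  expect_error(binarize_adversity(c(0, 1, 2), rule_binary()), "non-binary")
})

test_that("bottom decile never flags more than 10% of non-missing values", {
  for (s in 1:10) {
    x <- local({set.seed(s); rnorm(137)})
    f <- binarize_adversity(x, rule_bottom_decile())
    expect_lte(sum(f), ceiling(0.1 * length(x)))
    cut <- stats::quantile(x, 0.1, type = 7)
    expect_true(all(x[f == 1L] < cut))
  }
})

test_that("domain scores sum indicators and cap at 3+", {
  m <- rbind(c(0, 0, 0, 0, 0), c(1, 1, 1, 1, 1), c(1, 0, 1, 0, 0))
  sc <- domain_adversity_score(m)
  expect_identical(sc$raw_sum, c(0L, 5L, 2L))
  expect_identical(as.character(sc$capped_category), c("0", "3+", "2"))
  # capping an already-capped value is a no-op
  expect_identical(cap_score(pmin(sc$raw_sum, 3L)), sc$capped_category)
  expect_error(domain_adversity_score(rbind(c(1, NA))), "impute")
})

test_that("analytical sample keeps cases and controls and logs exclusions", {
  tab <- data.frame(derived_group = c(rep("case", 3), rep("control", 4),
                                      rep("excluded_role_only", 2),
                                      "excluded_mltc_only"))
  out <- select_analytical_sample(tab)
  expect_identical(nrow(out), 7L)
  expect_identical(attr(out, "exclusion_counts"),
                   c(excluded_role_only = 2L, excluded_mltc_only = 1L,
                     group_missing = 0L))
  # no exclusions: unchanged; empty: empty
  clean <- data.frame(derived_group = c("case", "control"))
  expect_identical(select_analytical_sample(clean)$derived_group,
                   clean$derived_group)
  expect_identical(nrow(select_analytical_sample(clean[0, , drop = FALSE])), 0L)
})

test_that("frozen cutoffs reproduce the original binarization", {
  spec <- default_bcs70_spec(n_participants = 300L)
  tab <- derive_scores(generate_cohort(spec, seed = 44), spec$domain_specs)
  cuts <- attr(tab, "cutoffs")
  again <- derive_scores(tab[names(tab) != "derived_balance_left_leg"],
                         spec$domain_specs, cutoffs = cuts)
  expect_identical(again$derived_balance_left_leg, tab$derived_balance_left_leg)
})
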