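# Scenario PAFs by model-based standardization.

test_that("a degenerate scenario (from == to) gives PAF exactly 0", {
  tab <- small_paf_fixture(seed = 402, n = 400L)
  an <- select_analytical_sample(tab)
  doms <- c("prenatal", "development")
  X <- build_model_design(an, 2L, doms)
  fit <- fit_logistic_mle(X, an$derived_case)
  sc <- paf_scenario_spec("prenatal", "1", "1")
  est <- paf_scenario(fit, an, sc, ci = "none", model_level = 2L, domains = doms)
  expect_identical(est$paf, 0)
})

test_that("saturated single-exposure model reduces PAF to 1 - p0/p1", {
  # single binary exposure, no covariates: standardized risks equal the
  # group outcome means, so PAF = 1 - mean(unexposed)/mean(exposed)
  x <- c(rep(1, 200), rep(0, 200))
  y <- c(rep(1, 40), rep(0, 160), rep(1, 20), rep(0, 180))  # 0.2 vs 0.1
  tab <- data.frame(
    sex_female = 0, ethnicity_nonwhite = 0, derived_case = y,
    derived_score_solo = x,
    derived_score_solo_cat = factor(ifelse(x == 1, "1", "0"),
                                    levels = c("0", "1", "2", "3+")))
  X <- cbind(`(Intercept)` = 1, score_solo_1 = x)
  fit <- fit_logistic_mle(X, y)
  est <- suppressWarnings(
    paf_scenario(fit, tab, paf_scenario_spec("solo", "1", "0"),
                 ci = "none", model_level = 2L))
  expect_equal(est$paf, 0.5, tolerance = 1e-9)
})

test_that("paf_scenario matches the brute-force standardization oracle", {
  tab <- small_paf_fixture(seed = 403, n = 50L)
  an <- tab  # keep all 50 rows; outcome groups all present as 0/1 case flag
  an$derived_case <- as.integer(an$derived_group == "case")
  doms <- detect_domains_of(an)
  X <- suppressWarnings(build_model_design(an, 2L, doms))
  fit <- suppressWarnings(fit_logistic_mle(X, an$derived_case))
  for (sc in list(paf_scenario_spec("prenatal", "1", "0"),
                  paf_scenario_spec("development", "2", "0"))) {
    expo <- which(an[[paste0("derived_score_", sc$domain, "_cat")]] == sc$from)
    if (!length(expo)) next
    est <- suppressWarnings(
      paf_scenario(fit, an, sc, ci = "none", model_level = 2L))
    # oracle: average the two predicted-probability vectors directly
    Xf <- X[expo, , drop = FALSE]
    Xc <- Xf
    own <- intersect(paste0("score_", sc$domain, c("_1", "_2", "_3plus")),
                     colnames(X))
    Xc[, own] <- 0
    if (sc$to != "0") Xc[, paste0("score_", sc$domain, "_", sc$to)] <- 1
    pf <- mean(stats::plogis(drop(Xf %*% fit$coefficients)))
    pc <- mean(stats::plogis(drop(Xc %*% fit$coefficients)))
    expect_lt(abs(est$paf - (1 - pc / pf)), 1e-12)
  }
})

test_that("PAF is invariant to row order and empty exposure groups error", {
  tab <- small_paf_fixture(seed = 404, n = 600L)
  an <- select_analytical_sample(tab)
  doms <- c("prenatal", "development")
  X <- build_model_design(an, 2L, doms)
  fit <- suppressWarnings(fit_logistic_mle(X, an$derived_case))
  sc <- paf_scenario_spec("development", "1", "0")
  a <- paf_scenario(fit, an, sc, ci = "none", model_level = 2L, domains = doms)
  perm <- an[rev(seq_len(nrow(an))), , drop = FALSE]
  b <- paf_scenario(fit, perm, sc, ci = "none", model_level = 2L, domains = doms)
  expect_equal(a$paf, b$paf, tolerance = 1e-12)

  none <- an[an$derived_score_development_cat != "3+", , drop = FALSE]
  expect_error(
    suppressWarnings(paf_scenario(fit, none, paf_scenario_spec("development", "3+", "0"),
                                  ci = "none", model_level = 2L, domains = doms)),
    "no participants")
})

test_that("non-negative score coefficients with to < from give PAF >= 0", {
  tab <- small_paf_fixture(seed = 405, n = 800L)
  an <- select_analytical_sample(tab)
  doms <- c("prenatal", "development")
  X <- build_model_design(an, 2L, doms)
  fit <- suppressWarnings(fit_logistic_mle(X, an$derived_case))
  # force the sign contract by construction
  sc_cols <- grep("^score_", names(fit$coefficients))
  fit$coefficients[sc_cols] <- abs(fit$coefficients[sc_cols])
  for (sc in default_paf_scenarios("prenatal")) {
    est <- tryCatch(paf_scenario(fit, an, sc, ci = "none", model_level = 2L,
                                 domains = doms),
                    error = function(e) NULL)
    if (!is.null(est)) expect_gte(est$paf, 0)
  }
})

test_that("monotone dose-response gives monotone 3+ scenario PAFs", {
  ok <- 0L; n_rep <- 8L
  for (s in seq_len(n_rep)) {
    spec <- default_bcs70_spec(n_participants = 3000L)
    spec$missingness$rates[] <- 0
    spec$outcome_coefficients[["score_development"]] <- 0.5
    an <- select_analytical_sample(derived_complete_cohort(spec, seed = 500 + s))
    doms <- c("prenatal", "development")
    X <- build_model_design(an, 2L, doms)
    fit <- suppressWarnings(fit_logistic_mle(X, an$derived_case))
    pafs <- vapply(c("2", "1", "0"), function(to) {
      paf_scenario(fit, an, paf_scenario_spec("development", "3+", to),
                   ci = "none", model_level = 2L, domains = doms)$paf
    }, numeric(1))
    if (pafs[["0"]] >= pafs[["1"]] && pafs[["1"]] >= pafs[["2"]]) ok <- ok + 1L
  }
  expect_gte(ok, ceiling(0.9 * n_rep))
})

test_that("pooled PAF over identical complete tables equals the single-dataset PAF", {
  spec <- default_bcs70_spec(n_participants = 2000L)
  spec$missingness$rates[] <- 0
  an <- select_analytical_sample(derived_complete_cohort(spec, seed = 58))
  doms <- c("prenatal", "development")
  X <- build_model_design(an, 3L, doms)
  fit <- suppressWarnings(fit_logistic_mle(X, an$derived_case))
  sc <- paf_scenario_spec("development", "1", "0")
  single <- paf_scenario(fit, an, sc, ci = "delta", model_level = 3L,
                         domains = doms)
  pooled <- paf_pooled(list(an, an), list(fit, fit), sc, ci = "delta",
                       model_level = 3L, domains = doms)
  expect_equal(pooled$paf, single$paf, tolerance = 1e-12)
  expect_equal(pooled$ci_low, single$ci_low, tolerance = 1e-9)
})

test_that("bootstrap and delta intervals roughly agree on a well-behaved fit", {
  spec <- default_bcs70_spec(n_participants = 2500L)
  spec$missingness$rates[] <- 0
  an <- select_analytical_sample(derived_complete_cohort(spec, seed = 59))
  doms <- c("prenatal", "development")
  X <- build_model_design(an, 2L, doms)
  fit <- fit_logistic_mle(X, an$derived_case)
  sc <- paf_scenario_spec("development", "1", "0")
  de <- paf_scenario(fit, an, sc, ci = "delta", model_level = 2L,
                     domains = doms)
  bo <- paf_scenario(fit, an, sc, ci = "bootstrap", boot_reps = 120L,
                     seed = 60, model_level = 2L, domains = doms)
  expect_equal(bo$paf, de$paf, tolerance = 1e-12)  # point estimate unaffected
  expect_lt(abs(sqrt(bo$var_log_puf) - sqrt(de$var_log_puf)),
            0.6 * sqrt(de$var_log_puf))
  # bootstrap is seed-reproducible
  bo2 <- paf_scenario(fit, an, sc, ci = "bootstrap", boot_reps = 120L,
                      seed = 60, model_level = 2L, domains = doms)
  expect_identical(bo$ci_low, bo2$ci_low)
})

test_that("paf_table screens domains by model-3 significance", {
  spec <- default_bcs70_spec(n_participants = 4000L)
  spec$missingness$rates[] <- 0
  spec$outcome_coefficients[["score_development"]] <- 0.6
  tabs <- analysis_tables(spec, seed = 61, M = 1L, miss = FALSE)
  m3 <- nested_domain_models(tabs, 3L)
  pt <- paf_table(tabs, models = m3, ci = "delta")
  if (nrow(pt$grid)) {
    expect_true(all(pt$grid$domain %in% significant_domains(m3)))
    expect_identical(nrow(pt$grid) %% 6L, 0L)  # six scenarios per domain
  }
  # explicit domain override bypasses the screen
  pt2 <- paf_table(tabs, models = m3, domains = "education", ci = "delta")
  expect_identical(unique(pt2$grid$domain), "education")
})
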