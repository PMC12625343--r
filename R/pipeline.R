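#' Configure a full study run
#'
#' Bundles every knob of the five-step pipeline. All four seed streams
#' are explicit and are recorded in the run manifest, so a manifest
#' suffices to reproduce a run bit-for-bit.
#'
#' @param mode `"synthetic"` (generate a cohort from `spec`) or `"csv"`
#'   (read `csv_path` validated against `dictionary_path`).
#' @param spec a [cohort_spec()]; defaults to [default_bcs70_spec()].
#' @param csv_path,dictionary_path input files for `mode = "csv"`.
#' @param M,cycles imputation settings (study defaults: 50 imputed
#'   datasets, 10 chained-equation cycles).
#' @param adult_coding adult-factor coding in Model 3 (see
#'   [build_model_design()]).
#' @param ci_method,boot_reps PAF interval settings (see
#'   [paf_scenario()]).
#' @param effects intervention library (default:
#'   [intervention_library()]).
#' @param seeds named list with `cohort`, `imputation`, `intervention`,
#'   `bootstrap` integer seeds.
#' @param output_dir run directory (created by [run_study()]).
#' @param persist_imputations write the M completed CSVs (can be large)?
#' @return a `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "csv"), spec = NULL,
                       csv_path = NULL, dictionary_path = NULL,
                       M = 50L, cycles = 10L,
                       adult_coding = c("linear", "dummy"),
                       ci_method = c("bootstrap", "delta"), boot_reps = 200L,
                       effects = intervention_library(),
                       seeds = list(cohort = 1L, imputation = 2L,
                                    intervention = 3L, bootstrap = 4L),
                       output_dir = "mltcprev_run",
                       persist_imputations = TRUE) {
  mode <- match.arg(mode)
  adult_coding <- match.arg(adult_coding)
  ci_method <- match.arg(ci_method)
  need <- c("cohort", "imputation", "intervention", "bootstrap")
  if (!all(need %in% names(seeds))) {
    stop("run_config: seeds must name ", paste(need, collapse = ", "))
  }
  # csv mode still needs the spec for adversity rules and column roles
  if (is.null(spec)) spec <- default_bcs70_spec()
  if (mode == "csv" && is.null(csv_path)) {
    stop("run_config: csv mode needs `csv_path`")
  }
  structure(list(mode = mode, spec = spec, csv_path = csv_path,
                 dictionary_path = dictionary_path, M = as.integer(M),
                 cycles = as.integer(cycles), adult_coding = adult_coding,
                 ci_method = ci_method, boot_reps = as.integer(boot_reps),
                 effects = effects, seeds = lapply(seeds, as.integer),
                 output_dir = output_dir,
                 persist_imputations = isTRUE(persist_imputations)),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the five-step study end-to-end
#'
#' Orchestrates: cohort acquisition (synthetic generation with
#' missing-at-random missingness, or CSV import), outcome derivation and
#' analytical-sample selection, chained-equations multiple imputation
#' with deletion of originally-missing outcomes, nested models 1-3 with
#' Rubin-pooled odds ratios, scenario PAFs for the significant domains,
#' and the counterfactual intervention simulation with transition tables
#' and projected absolute risk reductions. Artefacts are written to the
#' configured directory as CSV/JSON plus a JSON run manifest; partial
#' outputs are retained when a stage fails.
#'
#' @param config a [run_config()].
#' @param quiet suppress stage messages?
#' @return invisibly, a list with the in-memory results (`cohort`,
#'   `analytical`, `imputed`, `models`, `pafs`, `transitions`,
#'   `scenarios`, `manifest`) and the run directory in `$dir`.
#' @export
run_study <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- file.path
  say <- function(...) if (!quiet) message("[mltcprev] ", ...)
  dspecs <- if (!is.null(config$spec)) config$spec$domain_specs else NULL

  say("stage cohort")
  cohort <- stage("cohort", {
    if (config$mode == "synthetic") {
      tab <- generate_cohort(config$spec, seed = config$seeds$cohort)
      tab <- inject_missingness(tab, config$spec, seed = config$seeds$cohort)
      tab
    } else {
      report <- validate_input_csv(config$csv_path, config$dictionary_path)
      if (nrow(report)) {
        stop("input validation failed with ", nrow(report), " violation(s)")
      }
      import_cohort(config$csv_path, config$dictionary_path)
    }
  })
  export_cohort(cohort, out(config$output_dir, "cohort.csv"), spec = config$spec)

  say("stage derive")
  analytical <- stage("derive", {
    tab <- derive_outcome(cohort)
    select_analytical_sample(tab)
  })
  exclusions <- attr(analytical, "exclusion_counts")
  utils::write.csv(analytical, out(config$output_dir, "derived_cohort.csv"),
                   row.names = FALSE, na = "")

  say("stage impute (M = ", config$M, ")")
  imputed <- stage("impute", {
    raw_vars <- unlist(lapply(dspecs, function(d) names(d$variables)))
    adult <- vapply(config$spec$adult_covariate_specs, `[[`, "", "name")
    cols <- intersect(c("sex_female", "ethnicity_nonwhite", raw_vars, adult,
                        "derived_case"), names(analytical))
    imp <- impute_chained(analytical,
                          variable_models = c(weekly_income = "lognormal"),
                          M = config$M, cycles = config$cycles,
                          seed = config$seeds$imputation, columns = cols)
    drop_imputed_outcomes(imp, "derived_case")
  })
  if (config$persist_imputations) {
    export_imputation_set(imputed, out(config$output_dir, "imputation"))
  } else {
    export_imputation_set_manifest_only(imputed,
                                        out(config$output_dir, "imputation"))
  }

  say("stage model")
  tables <- stage("model-derive", {
    lapply(imputed$tables, derive_scores, domain_specs = dspecs)
  })
  models <- stage("model", {
    lapply(1:3, function(lv) {
      nested_domain_models(tables, lv, adult_coding = config$adult_coding)
    })
  })
  or_all <- do.call(rbind, lapply(models, `[[`, "or_table"))
  utils::write.csv(or_all, out(config$output_dir, "or_table.csv"),
                   row.names = FALSE)
  jsonlite::write_json(or_all, out(config$output_dir, "or_table.json"),
                       dataframe = "rows", digits = NA)

  say("stage paf")
  pafs <- stage("paf", {
    paf_table(tables, models = models[[3]], model_level = 3L,
              ci = config$ci_method, boot_reps = config$boot_reps,
              seed = config$seeds$bootstrap,
              adult_coding = config$adult_coding)
  })
  export_paf_table(pafs, out(config$output_dir, "paf_table.csv"),
                   out(config$output_dir, "paf_table.json"))

  say("stage simulate")
  lib_df <- do.call(rbind, lapply(config$effects, function(e) {
    data.frame(target = e$target_variable, kind = e$effect_kind,
               magnitude = e$magnitude, eligibility = e$eligibility,
               source = e$source, units = e$units, stringsAsFactors = FALSE)
  }))
  utils::write.csv(lib_df, out(config$output_dir, "intervention_library.csv"),
                   row.names = FALSE)
  jsonlite::write_json(lib_df, out(config$output_dir, "intervention_library.json"),
                       dataframe = "rows", digits = NA)

  sim <- stage("simulate", {
    # movers counted once, on the first completed analysis dataset
    ref <- tables[[1]]
    after <- apply_all(ref, config$effects, seed = config$seeds$intervention,
                       domain_specs = dspecs)
    after <- recompute_scores(after, dspecs)
    sig <- pafs$grid
    transitions <- list()
    scenarios <- list()
    for (d in unique(sig$domain)) {
      tt <- transition_table(ref[[paste0("derived_score_", d, "_cat")]],
                             after[[paste0("derived_score_", d, "_cat")]],
                             ref$derived_group, d)
      transitions[[d]] <- tt
      utils::write.csv(as.data.frame(tt$counts),
                       out(config$output_dir, paste0("transitions_", d, ".csv")),
                       row.names = FALSE)
      for (key in names(pafs$estimates)) {
        e <- pafs$estimates[[key]]
        if (e$scenario$domain != d) next
        if (!(e$ci_low > 0 | e$ci_high < 0)) next  # project significant PAFs only
        if (tt$group_sizes[e$scenario$from] == 0) next
        scenarios[[key]] <- project_reduction(tt, e)
      }
    }
    list(after = after, transitions = transitions, scenarios = scenarios)
  })

  if (length(sim$scenarios)) {
    sc_df <- do.call(rbind, lapply(names(sim$scenarios), function(k) {
      s <- sim$scenarios[[k]]
      data.frame(domain = s$scenario$domain,
                 scenario = scenario_label(s$scenario), movers = s$movers,
                 group_cases = s$group_cases, paf = s$paf,
                 removals_fractional = s$projected_removals_fractional,
                 removals_integer = s$projected_removals_integer,
                 arr_fractional_pct = s$arr_fractional_pct,
                 arr_integer_pct = s$arr_integer_pct,
                 stringsAsFactors = FALSE)
    }))
  } else {
    sc_df <- data.frame()
  }
  utils::write.csv(sc_df, out(config$output_dir, "scenario_results.csv"),
                   row.names = FALSE)
  jsonlite::write_json(sc_df, out(config$output_dir, "scenario_results.json"),
                       dataframe = "rows", digits = NA)
  if (length(sim$scenarios)) {
    best <- sim$scenarios[[which.max(vapply(sim$scenarios, function(s)
      s$projected_removals_integer, numeric(1)))]]
    writeLines(case_study_report(best),
               out(config$output_dir, "case_study.txt"))
  }

  analysed <- tables[[1]][!is.na(tables[[1]]$derived_case), , drop = FALSE]
  manifest <- list(
    package_version = as.character(utils::packageVersion("mltcprev")),
    mode = config$mode, n_input = nrow(cohort),
    exclusions = as.list(exclusions),
    n_analytical = nrow(analysed),
    case_prevalence = mean(analysed$derived_case),
    M = config$M, cycles = config$cycles,
    adult_coding = config$adult_coding, ci_method = config$ci_method,
    boot_reps = config$boot_reps, seeds = config$seeds,
    significant_domains = unique(pafs$grid$domain))
  jsonlite::write_json(manifest, out(config$output_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("done: ", config$output_dir)
  invisible(list(dir = config$output_dir, cohort = cohort,
                 analytical = analytical, imputed = imputed, tables = tables,
                 models = models, pafs = pafs,
                 transitions = sim$transitions, scenarios = sim$scenarios,
                 manifest = manifest))
}

export_imputation_set_manifest_only <- function(imputation_set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(M = imputation_set$M, cycles = imputation_set$cycles,
                   seed = imputation_set$seed,
                   missing_counts = as.list(colSums(imputation_set$original_na)),
                   dropped_rows = length(imputation_set$dropped_rows %||% integer(0)),
                   log = imputation_set$log)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
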