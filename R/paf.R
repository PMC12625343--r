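# Scenario-specific population attributable fractions by model-based
# standardization (G-computation): among participants observed at the
# scenario's "from" score category, average the fitted model's predicted
# case probabilities at the observed covariates (factual), then with the
# domain's score dummies switched to the "to" category with everything
# else fixed (counterfactual). PUF = p_counterfactual / p_factual is the
# ratio of standardized risks; PAF = 1 - PUF.

#' Declare a PAF scenario
#'
#' @param domain domain name.
#' @param from score category whose members are standardized (`"1"`,
#'   `"2"` or `"3+"`).
#' @param to counterfactual score category (`"0"`, `"1"` or `"2"`),
#'   strictly below `from`. Equal categories are allowed as a degenerate
#'   case (PAF exactly 0).
#' @return a `paf_scenario_spec` list.
#' @export
paf_scenario_spec <- function(domain, from, to) {
  from <- as.character(from); to <- as.character(to)
  stopifnot(from %in% c("1", "2", "3+"), to %in% c("0", "1", "2", "3+"))
  if (match(to, score_levels) > match(from, score_levels)) {
    stop("paf_scenario_spec: `to` must not exceed `from`")
  }
  structure(list(domain = domain, from = from, to = to),
            class = "paf_scenario_spec")
}

#' The six standard reduction scenarios for one domain
#'
#' 3+ to 2, 3+ to 1, 3+ to 0, 2 to 1, 2 to 0, and 1 to 0.
#'
#' @param domain domain name.
#' @return list of [paf_scenario_spec()]s.
#' @export
default_paf_scenarios <- function(domain) {
  list(paf_scenario_spec(domain, "3+", "2"), paf_scenario_spec(domain, "3+", "1"),
       paf_scenario_spec(domain, "3+", "0"), paf_scenario_spec(domain, "2", "1"),
       paf_scenario_spec(domain, "2", "0"), paf_scenario_spec(domain, "1", "0"))
}

scenario_label <- function(s) paste0(s$from, " to ", s$to)

# switch a domain's score dummy columns in a design matrix to `to`
switch_score_columns <- function(X, domain, to) {
  cols <- intersect(paste0("score_", domain, c("_1", "_2", "_3plus")),
                    colnames(X))
  X[, cols] <- 0
  target <- paste0("score_", domain, "_",
                   if (to == "3+") "3plus" else to)
  if (to != "0") {
    if (!target %in% colnames(X)) {
      stop("counterfactual category dummy not in design: ", target)
    }
    X[, target] <- 1
  }
  X
}

#' Scenario PAF on a single completed dataset
#'
#' @param fit a `model_fit` (a fully adjusted logistic model).
#' @param tab the completed analysis table the model was fitted on (must
#'   carry derived scores and `derived_case`).
#' @param scenario a [paf_scenario_spec()].
#' @param ci `"delta"` (analytic, on the log-PUF scale through the Wald
#'   covariance of the coefficients), `"bootstrap"` (resample rows,
#'   refit, percentile interval; seeded), or `"none"`.
#' @param boot_reps bootstrap resamples (default 200).
#' @param seed seed for the bootstrap stream.
#' @param model_level,adult_coding design options matching the fit; used
#'   to rebuild the design (and refit under the bootstrap).
#' @param domains domain set of the fitted design; defaults to every
#'   domain with derived scores in the table.
#' @param conf confidence level.
#' @return a `paf_estimate`: `paf`, `log_puf`, `var_log_puf`, `ci_low`,
#'   `ci_high` (on the PAF scale), `n_exposed`, `scenario`.
#' @export
paf_scenario <- function(fit, tab, scenario, ci = c("delta", "bootstrap", "none"),
                         boot_reps = 200L, seed = 1L, model_level = 3L,
                         adult_coding = "linear", domains = NULL, conf = 0.95) {
  ci <- match.arg(ci)
  keep <- !is.na(tab$derived_case)
  tab <- tab[keep, , drop = FALSE]
  if (is.null(domains)) domains <- detect_domains(tab)
  cat_col <- paste0("derived_score_", scenario$domain, "_cat")
  exposed <- which(tab[[cat_col]] == scenario$from)
  if (!length(exposed)) {
    stop("paf_scenario: no participants in exposed group for scenario ",
         scenario$domain, " ", scenario_label(scenario))
  }
  X <- build_model_design(tab, model_level, domains, adult_coding)
  res <- paf_point(fit, X, exposed, scenario)

  est <- list(scenario = scenario, paf = res$paf, log_puf = res$log_puf,
              var_log_puf = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
              n_exposed = length(exposed), ci_method = ci, conf = conf)
  class(est) <- "paf_estimate"
  if (ci == "none" || scenario$from == scenario$to) {
    if (scenario$from == scenario$to) {
      est$var_log_puf <- 0; est$ci_low <- 0; est$ci_high <- 0
    }
    return(est)
  }
  if (ci == "delta") {
    v <- delta_var_log_puf(fit, X, exposed, scenario)
    q <- stats::qnorm(1 - (1 - conf) / 2)
    est$var_log_puf <- v
    est$ci_low <- 1 - exp(res$log_puf + q * sqrt(v))
    est$ci_high <- 1 - exp(res$log_puf - q * sqrt(v))
  } else {
    lp <- with_seed(derive_seed(seed, paste0("paf-boot-", scenario$domain, "-",
                                             scenario$from, scenario$to)), {
      vapply(seq_len(boot_reps), function(b) {
        idx <- sample.int(nrow(tab), replace = TRUE)
        tb <- tab[idx, , drop = FALSE]
        expo <- which(tb[[cat_col]] == scenario$from)
        if (!length(expo)) return(NA_real_)
        tryCatch({
          Xb <- suppressWarnings(
            build_model_design(tb, model_level, domains, adult_coding))
          fb <- suppressWarnings(
            fit_logistic_mle(Xb, tb$derived_case, max_iter = 50L, tol = 1e-8))
          paf_point(fb, Xb, expo, scenario)$log_puf
        }, error = function(e) NA_real_)
      }, numeric(1))
    })
    lp <- lp[is.finite(lp)]
    est$var_log_puf <- stats::var(lp)
    alpha <- (1 - conf) / 2
    qs <- stats::quantile(lp, c(1 - alpha, alpha), names = FALSE, type = 7)
    est$ci_low <- 1 - exp(qs[1])
    est$ci_high <- 1 - exp(qs[2])
  }
  est
}

# point computation shared by all CI routes; the direct average of the
# two predicted-probability vectors
paf_point <- function(fit, X, exposed, scenario) {
  Xf <- X[exposed, , drop = FALSE]
  Xc <- switch_score_columns(Xf, scenario$domain, scenario$to)
  pf <- mean(stats::plogis(drop(Xf %*% fit$coefficients[colnames(Xf)])))
  pc <- mean(stats::plogis(drop(Xc %*% fit$coefficients[colnames(Xc)])))
  log_puf <- log(pc) - log(pf)
  list(paf = 1 - exp(log_puf), log_puf = log_puf, p_factual = pf,
       p_counterfactual = pc)
}

# delta-method variance of log PUF: gradient wrt beta of
# log mean(plogis(Xc b)) - log mean(plogis(Xf b)), then g' V g
delta_var_log_puf <- function(fit, X, exposed, scenario) {
  Xf <- X[exposed, , drop = FALSE]
  Xc <- switch_score_columns(Xf, scenario$domain, scenario$to)
  b <- fit$coefficients[colnames(Xf)]
  pf <- stats::plogis(drop(Xf %*% b))
  pc <- stats::plogis(drop(Xc %*% b))
  gf <- colMeans(Xf * (pf * (1 - pf))) / mean(pf)
  gc <- colMeans(Xc * (pc * (1 - pc))) / mean(pc)
  g <- gc - gf
  drop(t(g) %*% fit$vcov[names(b), names(b)] %*% g)
}

#' @export
print.paf_estimate <- function(x, ...) {
  cat("<paf_estimate>", x$scenario$domain, scenario_label(x$scenario),
      sprintf("| PAF = %.1f%% (%.1f%%, %.1f%%) | n exposed = %d\n",
              100 * x$paf, 100 * x$ci_low, 100 * x$ci_high, x$n_exposed))
  invisible(x)
}

#' Pooled scenario PAF across imputed datasets
#'
#' Computes the scenario PAF in each completed table with its own
#' fully-adjusted fit, pools log PUF and its variance by Rubin's rules,
#' and back-transforms the pooled interval to the PAF scale.
#'
#' @param tables list of completed analysis tables with derived scores.
#' @param fits list of per-table `model_fit`s (same length).
#' @param scenario a [paf_scenario_spec()].
#' @inheritParams paf_scenario
#' @return a `paf_estimate` with pooling metadata (`M`, `df`).
#' @export
paf_pooled <- function(tables, fits, scenario, ci = c("delta", "bootstrap"),
                       boot_reps = 200L, seed = 1L, model_level = 3L,
                       adult_coding = "linear", domains = NULL, conf = 0.95) {
  ci <- match.arg(ci)
  stopifnot(length(tables) == length(fits))
  per <- Map(function(tb, f) {
    paf_scenario(f, tb, scenario, ci = ci, boot_reps = boot_reps, seed = seed,
                 model_level = model_level, adult_coding = adult_coding,
                 domains = domains, conf = conf)
  }, tables, fits)
  if (length(per) == 1L) {
    est <- per[[1]]
    est$M <- 1L
    return(est)
  }
  lp <- vapply(per, `[[`, numeric(1), "log_puf")
  va <- vapply(per, `[[`, numeric(1), "var_log_puf")
  pl <- pool_rubin(lp, va, conf)
  q <- if (is.finite(pl$df)) stats::qt(1 - (1 - conf) / 2, pl$df) else
    stats::qnorm(1 - (1 - conf) / 2)
  structure(list(scenario = scenario, paf = 1 - exp(pl$estimate),
                 log_puf = pl$estimate, var_log_puf = pl$T,
                 ci_low = 1 - exp(pl$estimate + q * pl$se),
                 ci_high = 1 - exp(pl$estimate - q * pl$se),
                 n_exposed = per[[1]]$n_exposed, ci_method = ci, conf = conf,
                 M = length(per), df = pl$df),
            class = "paf_estimate")
}

#' Scenario PAF grid for the significant domains
#'
#' For each domain significantly associated with the outcome in the
#' fully adjusted model, computes the six standard reduction scenarios,
#' pooled across imputations. With no significant domain the grid is
#' empty and a notice is logged via `message()`.
#'
#' @param x an `imputation_set` or list of completed analysis tables
#'   (with derived scores).
#' @param models optional precomputed `nested_models` at the chosen
#'   level; refitted here when absent.
#' @param model_level model used for adjustment and significance
#'   (default 3, the fully adjusted model).
#' @param domains optional explicit domain set, overriding the
#'   significance screen.
#' @inheritParams paf_scenario
#' @return a `paf_table` object: `grid` (data.frame: domain, scenario,
#'   paf, ci_low, ci_high, significant, n_exposed) and `estimates` (the
#'   `paf_estimate` objects).
#' @export
paf_table <- function(x, models = NULL, model_level = 3L, domains = NULL,
                      ci = c("delta", "bootstrap"), boot_reps = 200L,
                      seed = 1L, adult_coding = "linear", conf = 0.95) {
  ci <- match.arg(ci)
  tables <- if (inherits(x, "imputation_set")) x$tables else x
  if (is.null(models)) {
    models <- nested_domain_models(tables, model_level,
                                   adult_coding = adult_coding, conf = conf)
  }
  fits <- models$fits[["all"]]
  if (is.null(fits)) stop("paf_table: needs a model-2/3 style joint fit")
  if (is.null(domains)) domains <- significant_domains(models)
  if (!length(domains)) {
    message("paf_table: no domain significant at model ", model_level,
            "; returning empty grid")
    return(structure(list(grid = data.frame(), estimates = list()),
                     class = "paf_table"))
  }
  # analysis rows must match the rows the fits used
  tables <- lapply(tables, function(tb) tb[!is.na(tb$derived_case), , drop = FALSE])
  ests <- list()
  for (d in domains) {
    for (sc in default_paf_scenarios(d)) {
      key <- paste0(d, ":", scenario_label(sc))
      ests[[key]] <- paf_pooled(tables, fits, sc, ci = ci,
                                boot_reps = boot_reps, seed = seed,
                                model_level = model_level,
                                adult_coding = adult_coding, conf = conf)
    }
  }
  grid <- do.call(rbind, lapply(names(ests), function(k) {
    e <- ests[[k]]
    data.frame(domain = e$scenario$domain, scenario = scenario_label(e$scenario),
               paf = e$paf, ci_low = e$ci_low, ci_high = e$ci_high,
               significant = e$ci_low > 0 | e$ci_high < 0,
               n_exposed = e$n_exposed, stringsAsFactors = FALSE)
  }))
  rownames(grid) <- NULL
  structure(list(grid = grid, estimates = ests), class = "paf_table")
}

#' @export
print.paf_table <- function(x, ...) {
  if (!nrow(x$grid)) {
    cat("<paf_table> empty (no significant domain)\n")
    return(invisible(x))
  }
  g <- x$grid
  g$paf <- sprintf("%.1f%%", 100 * g$paf)
  g$ci <- sprintf("%.1f%% - %.1f%%", 100 * x$grid$ci_low, 100 * x$grid$ci_high)
  print(g[, c("domain", "scenario", "paf", "ci", "significant", "n_exposed")])
  invisible(x)
}

#' Export a PAF grid as CSV / JSON
#'
#' @param pt a `paf_table`.
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @return invisibly, the grid.
#' @export
export_paf_table <- function(pt, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) utils::write.csv(pt$grid, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(pt$grid, json_path, dataframe = "rows", digits = NA)
  }
  invisible(pt$grid)
}
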