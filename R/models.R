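# Nested logistic models of MLTCs-with-role-limitation on domain
# adversity scores:
#   Model 1 — one fit per domain: that domain's score dummies + sex + ethnicity
#   Model 2 — all five domains' dummies + sex + ethnicity
#   Model 3 — Model 2 + adult factors at age 46
# Score categories enter as indicators against reference 0.

adult_factor_names <- function() {
  c("exercise_days", "education_level", "nssec", "log_income_z", "smoker",
    "tv_hours", "internet_hours", "partner", "imd_decile",
    "financial_difficulty", "audit_class")
}

# dummy columns for one domain's capped score: <domain>_1, _2, _3plus
score_dummies <- function(tab, domain) {
  cat <- tab[[paste0("derived_score_", domain, "_cat")]]
  if (is.null(cat)) stop("missing derived score for domain ", domain,
                         "; run derive_scores() first")
  out <- cbind(as.numeric(cat == "1"), as.numeric(cat == "2"),
               as.numeric(cat == "3+"))
  colnames(out) <- paste0("score_", domain, c("_1", "_2", "_3plus"))
  out
}

#' Build the design matrix for one nested model level
#'
#' @param tab a completed analysis table with derived score columns.
#' @param model_level 1, 2 or 3.
#' @param domains character vector of domain names; for Model 1 a single
#'   domain.
#' @param adult_coding `"linear"` enters ordered adult factors as single
#'   linear-in-code terms (default; keeps small fits stable), `"dummy"`
#'   expands them to full indicator sets.
#' @return numeric design matrix (with intercept). Columns that are empty
#'   in this table (an unpopulated score category) are dropped with a
#'   warning naming the collapsed category.
#' @export
build_model_design <- function(tab, model_level, domains,
                               adult_coding = c("linear", "dummy")) {
  adult_coding <- match.arg(adult_coding)
  stopifnot(model_level %in% 1:3)
  parts <- list(`(Intercept)` = rep(1, nrow(tab)))
  for (d in domains) parts[[d]] <- score_dummies(tab, d)
  parts$sex_female <- as.numeric(tab$sex_female)
  parts$ethnicity_nonwhite <- as.numeric(tab$ethnicity_nonwhite)
  if (model_level == 3L) {
    for (a in adult_factor_names()) {
      v <- if (a == "log_income_z") {
        li <- log(tab$weekly_income)
        s <- stats::sd(li)
        (li - mean(li)) / if (s > 0) s else 1
      } else {
        as.numeric(tab[[a]])
      }
      if (adult_coding == "dummy" && a %in% c("exercise_days", "tv_hours",
            "internet_hours", "imd_decile", "financial_difficulty",
            "education_level", "nssec", "audit_class")) {
        lev <- sort(unique(v))[-1]
        dm <- vapply(lev, function(l) as.numeric(v == l), numeric(nrow(tab)))
        colnames(dm) <- paste0(a, "_", lev)
        parts[[a]] <- dm
      } else {
        parts[[a]] <- v
      }
    }
  }
  X <- do.call(cbind, lapply(names(parts), function(nm) {
    p <- parts[[nm]]
    if (is.null(dim(p))) {
      p <- matrix(p, ncol = 1, dimnames = list(NULL, nm))
    }
    p
  }))
  empty <- colSums(abs(X)) == 0
  if (any(empty)) {
    warning("empty design column(s) collapsed: ",
            paste(colnames(X)[empty], collapse = ", "))
    X <- X[, !empty, drop = FALSE]
  }
  X
}

#' Fit the nested domain models across imputed datasets
#'
#' Fits the requested nested model specification in every completed
#' table, pools each coefficient across imputations on the log-odds
#' scale by [pool_rubin()], and reports odds ratios with 95% Wald
#' confidence intervals. With `M = 1` the "pooled" output equals the
#' single-dataset fit (degenerate pooling).
#'
#' @param x an `imputation_set` (tables must carry derived scores, or
#'   supply `domain_specs` to derive them here) or a list of completed
#'   data.frames.
#' @param model_level 1, 2 or 3; `1` fits one model per domain.
#' @param domain_specs optional list of [domain_spec()]s used to derive
#'   scores when absent from the tables.
#' @param adult_coding see [build_model_design()].
#' @param conf confidence level.
#' @return a `nested_models` object: `or_table` (data.frame with domain,
#'   score category, model, OR, CI, significance), `pooled` (pooled
#'   log-odds results per coefficient), `fits` (per-imputation
#'   `model_fit`s, named by domain for Model 1), `model_level`, `domains`.
#' @export
nested_domain_models <- function(x, model_level, domain_specs = NULL,
                                 adult_coding = c("linear", "dummy"),
                                 conf = 0.95) {
  adult_coding <- match.arg(adult_coding)
  tables <- if (inherits(x, "imputation_set")) x$tables else x
  if (!is.null(domain_specs)) {
    need <- !all(paste0("derived_score_",
                        vapply(domain_specs, `[[`, "", "name")) %in%
                   names(tables[[1]]))
    if (need) tables <- lapply(tables, derive_scores, domain_specs = domain_specs)
  }
  domains <- detect_domains(tables[[1]])
  if (!length(domains)) stop("no derived score columns found")
  y_name <- "derived_case"
  if (!y_name %in% names(tables[[1]])) stop("tables lack derived_case")

  fit_block <- function(doms) {
    lapply(tables, function(tb) {
      keep <- !is.na(tb[[y_name]])
      tb <- tb[keep, , drop = FALSE]
      X <- build_model_design(tb, model_level, doms, adult_coding)
      fit_logistic_mle(X, tb[[y_name]])
    })
  }

  if (model_level == 1L) {
    fits <- lapply(domains, function(d) fit_block(d))
    names(fits) <- domains
  } else {
    fits <- list(all = fit_block(domains))
  }

  pooled <- list()
  for (block in names(fits)) {
    bf <- fits[[block]]
    common <- Reduce(intersect, lapply(bf, function(f) names(f$coefficients)))
    dropped <- setdiff(unique(unlist(lapply(bf, function(f)
      names(f$coefficients)))), common)
    if (length(dropped)) {
      warning("coefficient(s) absent from some imputations, not pooled: ",
              paste(dropped, collapse = ", "))
    }
    for (cf in common) {
      est <- vapply(bf, function(f) f$coefficients[[cf]], numeric(1))
      va <- vapply(bf, function(f) f$vcov[cf, cf], numeric(1))
      pl <- if (length(bf) == 1L) {
        q <- stats::qnorm(1 - (1 - conf) / 2)
        list(estimate = est, W = va, B = 0, T = va, se = sqrt(va), df = Inf,
             ci_low = est - q * sqrt(va), ci_high = est + q * sqrt(va), M = 1L)
      } else {
        pool_rubin(est, va, conf)
      }
      pooled[[paste(block, cf, sep = ".")]] <-
        c(list(block = block, term = cf), pl)
    }
  }

  or_rows <- list()
  for (d in domains) {
    block <- if (model_level == 1L) d else "all"
    for (lv in c("1", "2", "3plus")) {
      key <- paste(block, paste0("score_", d, "_", lv), sep = ".")
      if (!key %in% names(pooled)) next
      pl <- pooled[[key]]
      or_rows[[key]] <- data.frame(
        domain = d, score = sub("plus", "+", lv), model = model_level,
        or = exp(pl$estimate), ci_low = exp(pl$ci_low),
        ci_high = exp(pl$ci_high),
        significant = pl$ci_low > 0 | pl$ci_high < 0,
        stringsAsFactors = FALSE)
    }
  }
  or_table <- do.call(rbind, or_rows)
  rownames(or_table) <- NULL
  structure(list(or_table = or_table, pooled = pooled, fits = fits,
                 model_level = model_level, domains = domains,
                 adult_coding = adult_coding, M = length(tables)),
            class = "nested_models")
}

detect_domains <- function(tab) {
  nm <- grep("^derived_score_.*_cat$", names(tab), value = TRUE)
  sub("^derived_score_(.*)_cat$", "\\1", nm)
}

#' @export
print.nested_models <- function(x, ...) {
  cat("<nested_models> model", x$model_level, "| M =", x$M, "imputations\n")
  print(transform(x$or_table,
                  or = round(or, 2), ci_low = round(ci_low, 2),
                  ci_high = round(ci_high, 2)))
  invisible(x)
}

#' Domains significantly associated with the outcome at a model level
#'
#' A domain counts as significant when any of its score-category odds
#' ratios has a confidence interval excluding 1.
#'
#' @param models a `nested_models` object.
#' @return character vector of domain names.
#' @export
significant_domains <- function(models) {
  ot <- models$or_table
  unique(ot$domain[ot$significant])
}

#' Export an OR table as CSV / JSON
#'
#' @param models a `nested_models` object.
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @return invisibly, the OR table.
#' @export
export_or_table <- function(models, csv_path = NULL, json_path = NULL) {
  ot <- models$or_table
  if (!is.null(csv_path)) utils::write.csv(ot, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(ot, json_path, dataframe = "rows", digits = NA)
  }
  invisible(ot)
}
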