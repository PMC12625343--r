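#' Generate a synthetic cohort table
#'
#' Draws a complete wide per-participant table with the structure of a
#' 1970s British birth cohort: demographics, raw early-life variables in
#' five correlated adversity domains (one standard-normal latent factor
#' per domain, loading 0.5), adult covariates at age 46 that depend mildly
#' on total adversity, 22 long-term-condition flags and 7 SF-36
#' role-limitation items. Outcome-relevant columns are drawn from the
#' spec's logistic model: each participant's case propensity is
#' `plogis(eta)` with `eta` the declared linear predictor, the four
#' outcome groups (case / control / role-limitation-only /
#' MLTC-without-limitation) are assigned, and condition flags and SF-36
#' items are then constructed to be exactly consistent with the drawn
#' group — so downstream derivation recovers the generating truth.
#'
#' Identical `(spec, seed)` inputs yield bit-identical output.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer master seed; defaults to the seed stored in `spec`.
#' @return a `data.frame` with one row per participant and no missing
#'   cells; ground-truth group, linear predictor and case propensity are
#'   attached as the `"truth"` attribute (a data.frame), which CSV export
#'   deliberately does not persist.
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  validate_cohort_spec(spec)
  n <- spec$n_participants
  if (n == 0L) return(empty_cohort(spec))

  with_seed(derive_seed(seed, "cohort"), {
    tab <- data.frame(participant_id = sprintf("P%06d", seq_len(n)),
                      stringsAsFactors = FALSE)
    tab$sex_female <- stats::rbinom(n, 1L, 0.5)
    tab$ethnicity_nonwhite <- stats::rbinom(n, 1L, 0.04)

    # raw early-life variables: shared latent factor per domain, loading 0.5
    for (d in spec$domain_specs) {
      latent <- stats::rnorm(n)
      for (v in names(d$variables)) {
        g <- d$variables[[v]]$gen
        tab[[v]] <- switch(
          g$kind,
          binary = {
            z <- 0.5 * latent + stats::rnorm(n)
            as.integer(z > stats::qnorm(1 - g$prevalence) * sqrt(1.25))
          },
          normal = {
            sgn <- if (identical(g$adverse, "low")) -1 else 1
            z <- (sgn * 0.5 * latent + stats::rnorm(n)) / sqrt(1.25)
            x <- g$mean + g$sd * z
            if (!is.null(g$floor)) x <- pmax(x, g$floor)
            x
          },
          stop("unknown generation kind for variable ", v))
      }
    }

    # capped domain scores on the complete data drive the outcome model
    # and the adult-covariate dependence
    scores <- derive_true_scores(tab, spec$domain_specs)
    total <- rowSums(scores)

    for (ac in spec$adult_covariate_specs) {
      tab[[ac$name]] <- draw_adult_covariate(ac, total, n)
    }

    X <- outcome_design_matrix(spec, cbind(tab, scores))
    eta <- drop(X %*% spec$outcome_coefficients[colnames(X)])
    p <- stats::plogis(eta)

    case <- stats::rbinom(n, 1L, p) == 1L
    ex <- spec$outcome_structure$exclusion_rates
    u <- stats::runif(n)
    group <- ifelse(case, "case",
             ifelse(u < ex[["role_only"]], "excluded_role_only",
             ifelse(u < ex[["role_only"]] + ex[["mltc_only"]],
                    "excluded_mltc_only", "control")))

    tab <- cbind(tab, draw_outcome_columns(group, spec$outcome_structure))
    attr(tab, "truth") <- data.frame(group = group, eta = eta, p = p,
                                     stringsAsFactors = FALSE)
    tab
  })
}

# capped 0..3 numeric scores computed straight from complete raw data;
# internal to the generator (the derivation module re-derives them from
# scratch, which is what tests compare against)
derive_true_scores <- function(tab, domain_specs) {
  out <- lapply(domain_specs, function(d) {
    ind <- vapply(names(d$variables), function(v) {
      binarize_adversity(tab[[v]], d$variables[[v]]$rule)
    }, integer(nrow(tab)))
    if (nrow(tab) == 1L) ind <- matrix(ind, nrow = 1L)
    pmin(rowSums(ind), 3L)
  })
  names(out) <- paste0("score_", vapply(domain_specs, `[[`, "", "name"))
  as.data.frame(out)
}

draw_adult_covariate <- function(ac, total, n) {
  switch(
    ac$type,
    binary = {
      pr <- stats::plogis(stats::qlogis(ac$base) +
                            ac$direction * ac$shift * total)
      stats::rbinom(n, 1L, pr)
    },
    ordinal = {
      # latent-logistic threshold model; fixed thresholds from the base
      # marginal distribution, adversity shifts the latent location
      tau <- stats::qlogis(cumsum(ac$base)[-length(ac$base)])
      u <- ac$direction * ac$shift * total + stats::rlogis(n)
      ac$levels[1L + findInterval(u, tau)]
    },
    lognormal = {
      ml <- ac$base[["meanlog"]] + ac$direction * ac$shift * total
      exp(stats::rnorm(n, ml, ac$base[["sdlog"]]))
    },
    stop("unknown adult covariate type: ", ac$type))
}

#' Design matrix of the spec's outcome model
#'
#' Resolves the names of `spec$outcome_coefficients` against a table that
#' carries the generated columns plus `score_<domain>` capped scores;
#' `log_income_z` is the standardized log of `weekly_income` against the
#' spec's generating lognormal parameters. Used by the generator to build
#' the linear predictor, and by tests to refit the generating model.
#'
#' @param spec a `cohort_spec`.
#' @param tab data.frame with the required columns.
#' @return numeric matrix with columns in coefficient order.
#' @export
outcome_design_matrix <- function(spec, tab) {
  nm <- names(spec$outcome_coefficients)
  cols <- lapply(nm, function(term) {
    if (term == "(Intercept)") return(rep(1, nrow(tab)))
    if (term == "log_income_z") {
      inc <- vapply(spec$adult_covariate_specs, function(a)
        identical(a$name, "weekly_income"), logical(1))
      base <- spec$adult_covariate_specs[[which(inc)]]$base
      return((log(tab$weekly_income) - base[["meanlog"]]) / base[["sdlog"]])
    }
    if (!term %in% names(tab)) stop("outcome term not found in table: ", term)
    as.numeric(tab[[term]])
  })
  X <- do.call(cbind, cols)
  colnames(X) <- nm
  X
}

# condition flags and SF-36 items exactly consistent with each group
draw_outcome_columns <- function(group, os) {
  n <- length(group)
  prev <- os$ltc_prevalence
  k <- length(prev)
  mltc <- group %in% c("case", "excluded_mltc_only")
  counts <- integer(n)
  counts[mltc] <- 2L + stats::rpois(sum(mltc), os$ltc_extra_mean)
  counts[!mltc] <- stats::rbinom(sum(!mltc), 1L, os$control_one_ltc_prob)
  counts <- pmin(counts, k)

  flags <- matrix(0L, n, k, dimnames = list(NULL, names(prev)))
  w <- prev / sum(prev)
  for (i in which(counts > 0L)) {
    flags[i, sample.int(k, counts[i], prob = w)] <- 1L
  }

  limited <- group %in% c("case", "excluded_role_only")
  typ <- character(n)
  typ[limited] <- sample(names(os$limited_split), sum(limited),
                         replace = TRUE, prob = os$limited_split)
  phys <- limited & typ %in% c("phys_only", "both")
  emo <- limited & typ %in% c("emo_only", "both")

  items <- function(lim, m) {
    it <- matrix(stats::rbinom(n * m, 1L, os$item_one_prob), n, m)
    # non-limited rows must not be all-zero (mean of answered must exceed 0)
    allz <- !lim & rowSums(it) == 0L
    it[allz, 1L] <- 1L
    it[lim, ] <- 0L
    it
  }
  ph <- items(phys, 4L); colnames(ph) <- paste0("sf36_phys_", 1:4)
  em <- items(emo, 3L); colnames(em) <- paste0("sf36_emo_", 1:3)
  as.data.frame(cbind(flags, ph, em))
}

empty_cohort <- function(spec) {
  cols <- spec_column_names(spec)
  out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
  out$participant_id <- character(0)
  attr(out, "truth") <- data.frame(group = character(0), eta = numeric(0),
                                   p = numeric(0))
  out
}

#' Inject missing-at-random missingness into a complete cohort
#'
#' Per-variable missingness probability depends only on always-observed
#' columns — sex and one designated domain indicator — so the mechanism is
#' missing-at-random by construction. For each variable with a positive
#' target rate the intercept of the missingness logit is solved so the
#' *expected* missing fraction equals the target exactly given the
#' realized driver values; the realized fraction then fluctuates within
#' binomial error.
#'
#' @param table a complete cohort table from [generate_cohort()].
#' @param spec the generating `cohort_spec` (supplies `missingness`).
#' @param seed integer seed for the missingness stream.
#' @return the table with `NA`s punched in; the `"truth"` attribute (if
#'   present) is preserved.
#' @export
inject_missingness <- function(table, spec, seed = spec$seed) {
  m <- spec$missingness
  rates <- m$rates
  if (any(is.na(rates) | rates < 0 | rates > 1)) {
    stop("inject_missingness: rates must lie in [0, 1]")
  }
  if (nrow(table) == 0L || !length(rates) || all(rates == 0)) return(table)
  truth <- attr(table, "truth")
  shift <- m$sex_shift * table$sex_female
  if (!is.null(m$indicator) && m$indicator %in% names(table)) {
    shift <- shift + m$indicator_shift * table[[m$indicator]]
  }
  with_seed(derive_seed(seed, "missingness"), {
    for (v in names(rates)) {
      r <- rates[[v]]
      if (r <= 0) next
      if (!v %in% names(table)) stop("inject_missingness: unknown column ", v)
      alpha <- solve_missing_intercept(r, shift)
      mis <- stats::runif(nrow(table)) < stats::plogis(alpha + shift)
      table[[v]][mis] <- NA
    }
  })
  attr(table, "truth") <- truth
  table
}

# intercept so that mean plogis(alpha + shift) equals the target rate
solve_missing_intercept <- function(rate, shift) {
  if (rate >= 1) return(Inf)
  f <- function(a) mean(stats::plogis(a + shift)) - rate
  stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
}
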