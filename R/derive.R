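#' Derive a role-limitation flag from SF-36 items
#'
#' The SF-36 role-limitation subscales are scored as the mean of the
#' questions actually answered (4 physical items, 3 emotional items, each
#' 0/1 with 0 = "yes, limited"). A participant is flagged as limited when
#' that mean equals 0, i.e. every answered item reports limitation; the
#' flag is missing only when every item is missing.
#'
#' @param items numeric vector of 0/1/NA responses.
#' @param expected_count required item count (4 physical, 3 emotional).
#' @return `TRUE`, `FALSE`, or `NA` (all items missing).
#' @export
derive_role_limitation <- function(items, expected_count) {
  if (length(items) != expected_count) {
    stop("derive_role_limitation: expected ", expected_count, " items, got ",
         length(items))
  }
  bad <- !is.na(items) & !(items %in% c(0, 1))
  if (any(bad)) stop("derive_role_limitation: non-binary item value")
  if (all(is.na(items))) return(NA)
  mean(items, na.rm = TRUE) == 0
}

# vectorized row version over an item matrix
role_limitation_rows <- function(mat) {
  bad <- !is.na(mat) & !(mat %in% c(0, 1))
  if (any(bad)) stop("role limitation items must be 0/1 or missing")
  answered <- rowSums(!is.na(mat))
  out <- rowSums(mat, na.rm = TRUE) == 0 & answered > 0
  out[answered == 0] <- NA
  out
}

#' Assign the four outcome groups
#'
#' Cases report two or more long-term conditions (MLTCs) *and* role
#' limitation for a physical or emotional problem; controls report
#' neither. Participants with only one component of the composite —
#' role limitation without MLTCs, or MLTCs without role limitation — are
#' set aside so the control group is clean, and are excluded from the
#' analytical sample.
#'
#' With partially missing condition flags, MLTC status is still resolved
#' when determinable: at least two observed positive flags means MLTC;
#' too few possible positives (observed positives plus missing flags
#' below two) means no MLTC; anything else is indeterminate and the group
#' is missing (such rows are dropped after imputation, with a logged
#' count).
#'
#' @param ltc_flags numeric vector (one participant) or matrix (rows =
#'   participants) of 0/1/NA condition flags, 22 columns.
#' @param physical_limited,emotional_limited logical (or NA) flags from
#'   [derive_role_limitation()].
#' @return a data.frame with `ltc_count` (observed positives), `mltc`,
#'   `limited`, and `group` (one of `case`, `control`,
#'   `excluded_role_only`, `excluded_mltc_only`, or `NA`).
#' @export
derive_outcome_group <- function(ltc_flags, physical_limited, emotional_limited) {
  if (is.null(dim(ltc_flags))) ltc_flags <- matrix(ltc_flags, nrow = 1L)
  bad <- !is.na(ltc_flags) & !(ltc_flags %in% c(0, 1))
  if (any(bad)) stop("derive_outcome_group: condition flags must be 0/1 or missing")
  ones <- rowSums(ltc_flags == 1, na.rm = TRUE)
  nas <- rowSums(is.na(ltc_flags))
  mltc <- ifelse(ones >= 2, TRUE, ifelse(ones + nas < 2, FALSE, NA))

  limited <- ifelse(physical_limited %in% TRUE | emotional_limited %in% TRUE, TRUE,
             ifelse(is.na(physical_limited) | is.na(emotional_limited), NA, FALSE))

  group <- rep(NA_character_, length(mltc))
  known <- !is.na(mltc) & !is.na(limited)
  group[known & mltc & limited] <- "case"
  group[known & !mltc & !limited] <- "control"
  group[known & !mltc & limited] <- "excluded_role_only"
  group[known & mltc & !limited] <- "excluded_mltc_only"
  data.frame(ltc_count = as.integer(ones), mltc = mltc, limited = limited,
             group = group, stringsAsFactors = FALSE)
}

#' Domain adversity scores from derived indicators
#'
#' Sums the binary adversity indicators of one domain into a raw score
#' and caps it into the categories 0, 1, 2, "3+" (scores of three or more
#' are combined because very high scores are rare). Scores are computed
#' on completed data only: a missing indicator is an error directing the
#' caller to impute first.
#'
#' @param indicators 0/1 matrix or data.frame, one column per indicator.
#' @return data.frame with `raw_sum` and `capped_category` (factor with
#'   levels `0`, `1`, `2`, `3+`).
#' @export
domain_adversity_score <- function(indicators) {
  m <- as.matrix(indicators)
  if (anyNA(m)) {
    stop("domain_adversity_score: missing indicator values; impute before scoring")
  }
  if (!all(m %in% c(0, 1))) stop("domain_adversity_score: indicators must be 0/1")
  raw <- as.integer(rowSums(m))
  capped <- cap_score(raw)
  data.frame(raw_sum = raw, capped_category = capped)
}

# cap a raw score into the 0/1/2/3+ factor; idempotent on capped values
cap_score <- function(raw) {
  factor(ifelse(raw >= 3, "3+", as.character(raw)), levels = c("0", "1", "2", "3+"))
}

score_levels <- c("0", "1", "2", "3+")

#' Append derived outcome columns to a cohort table
#'
#' Computes, with a `derived_` prefix: per-subscale role-limitation flags,
#' the observed condition count, and the outcome group. Works on tables
#' with missing cells; indeterminable values stay missing.
#'
#' @param table cohort table with the 22 condition flags and SF-36 items.
#' @return the table with `derived_phys_limited`, `derived_emo_limited`,
#'   `derived_ltc_count`, `derived_mltc`, `derived_group` and
#'   `derived_case` appended.
#' @export
derive_outcome <- function(table) {
  ph <- as.matrix(table[paste0("sf36_phys_", 1:4)])
  em <- as.matrix(table[paste0("sf36_emo_", 1:3)])
  flags <- as.matrix(table[names(default_ltc_prevalence())])
  phys <- role_limitation_rows(ph)
  emo <- role_limitation_rows(em)
  lab <- derive_outcome_group(flags, phys, emo)
  table$derived_phys_limited <- phys
  table$derived_emo_limited <- emo
  table$derived_ltc_count <- lab$ltc_count
  table$derived_mltc <- lab$mltc
  table$derived_group <- lab$group
  table$derived_case <- ifelse(is.na(lab$group), NA_integer_,
                               as.integer(lab$group == "case"))
  table
}

#' Restrict to the analytical sample
#'
#' Keeps cases and controls (the clean comparison); rows in the two
#' excluded groups are removed and their counts recorded. Rows whose
#' group is still indeterminate (missing outcome components) are retained
#' here — the outcome is imputed but imputed outcome values are not used,
#' so those rows are deleted after imputation by
#' [drop_imputed_outcomes()].
#'
#' @param table a table carrying `derived_group`.
#' @return the filtered table; exclusion counts in the
#'   `"exclusion_counts"` attribute.
#' @export
select_analytical_sample <- function(table) {
  if (nrow(table) == 0L) {
    attr(table, "exclusion_counts") <-
      c(excluded_role_only = 0L, excluded_mltc_only = 0L, group_missing = 0L)
    return(table)
  }
  if (!"derived_group" %in% names(table)) {
    stop("select_analytical_sample: run derive_outcome() first")
  }
  g <- table$derived_group
  counts <- c(excluded_role_only = sum(g %in% "excluded_role_only"),
              excluded_mltc_only = sum(g %in% "excluded_mltc_only"),
              group_missing = sum(is.na(g)))
  keep <- is.na(g) | g %in% c("case", "control")
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusion_counts") <- counts
  out
}

#' Derive adversity indicators and domain scores
#'
#' Applies each variable's adversity rule, appends `derived_<variable>`
#' indicator columns, and — when the data are complete — the capped
#' domain scores `derived_score_<domain>` (numeric 0..3) and
#' `derived_score_<domain>_cat` (factor). Bottom-decile cutoffs are
#' computed on this table's non-missing values and frozen in the
#' `"cutoffs"` attribute so counterfactual re-derivation reuses them.
#'
#' @param table cohort table (typically one completed/imputed copy).
#' @param domain_specs list of [domain_spec()] objects.
#' @param scores compute domain scores too? Requires complete indicators;
#'   set `FALSE` to derive indicators on data that still has missing
#'   cells.
#' @param cutoffs optional named cutoff vector to reuse (overrides
#'   recomputation; used for counterfactual re-derivation).
#' @return the augmented table.
#' @export
derive_scores <- function(table, domain_specs, scores = TRUE, cutoffs = NULL) {
  used <- c()
  for (d in domain_specs) {
    for (v in names(d$variables)) {
      rule <- d$variables[[v]]$rule
      cut <- if (!is.null(cutoffs) && v %in% names(cutoffs)) cutoffs[[v]] else NULL
      table[[paste0("derived_", v)]] <-
        binarize_adversity(table[[v]], rule, cutoff = cut)
      used[v] <- cut %||% rule_cutoff(table[[v]], rule)
    }
    if (scores) {
      ind <- table[paste0("derived_", names(d$variables))]
      sc <- domain_adversity_score(ind)
      table[[paste0("derived_score_", d$name)]] <-
        pmin(sc$raw_sum, 3L)
      table[[paste0("derived_score_", d$name, "_cat")]] <- sc$capped_category
    }
  }
  attr(table, "cutoffs") <- used
  table
}

#' Recompute domain scores from the current indicators
#'
#' Unlike [derive_scores()], this does not re-binarize raw variables; it
#' sums the `derived_<variable>` indicator columns as they stand. Used
#' after counterfactual intervention effects, where reclassified
#' indicators must keep their new values.
#'
#' @param table a table with complete `derived_<variable>` columns.
#' @param domain_specs list of [domain_spec()] objects.
#' @return the table with refreshed `derived_score_*` columns.
#' @export
recompute_scores <- function(table, domain_specs) {
  for (d in domain_specs) {
    ind <- table[paste0("derived_", names(d$variables))]
    sc <- domain_adversity_score(ind)
    table[[paste0("derived_score_", d$name)]] <- pmin(sc$raw_sum, 3L)
    table[[paste0("derived_score_", d$name, "_cat")]] <- sc$capped_category
  }
  table
}
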