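#' Adversity derivation rules
#'
#' Every raw early-life variable is reduced to a binary adversity indicator
#' (1 = adversity) before domain scores are formed. Four rule types cover
#' the cases that arise in practice:
#'
#' * `rule_binary()` — the variable is already a 0/1 adversity report and is
#'   taken as-is.
#' * `rule_threshold_below(cutoff, units)` — adversity when the value is
#'   strictly below a validated cutoff (e.g. birthweight under 2500 g, the
#'   WHO low-birthweight convention).
#' * `rule_threshold_above(cutoff, units)` — adversity when strictly above a
#'   cutoff (e.g. a high-risk score on a behaviour screening scale).
#' * `rule_bottom_decile()` — a pragmatic rule for variables without an
#'   accepted cutoff: adversity when the value lies strictly below the
#'   empirical 10th percentile of the cohort distribution (type-7
#'   linear-interpolation percentile). Ties at the cutoff are not adverse.
#'
#' @param cutoff numeric cutoff in the variable's natural units.
#' @param units character label for the cutoff units (documentation only).
#' @return a rule object (class `adversity_rule`).
#' @name adversity_rules
NULL

new_rule <- function(kind, cutoff = NULL, units = NULL) {
  structure(list(kind = kind, cutoff = cutoff, units = units),
            class = "adversity_rule")
}

#' @rdname adversity_rules
#' @export
rule_binary <- function() new_rule("binary_as_is")

#' @rdname adversity_rules
#' @export
rule_threshold_below <- function(cutoff, units = "") {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, is.finite(cutoff))
  new_rule("threshold_below", cutoff, units)
}

#' @rdname adversity_rules
#' @export
rule_threshold_above <- function(cutoff, units = "") {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, is.finite(cutoff))
  new_rule("threshold_above", cutoff, units)
}

#' @rdname adversity_rules
#' @export
rule_bottom_decile <- function() new_rule("bottom_decile")

#' @export
print.adversity_rule <- function(x, ...) {
  cat("<adversity_rule>", x$kind)
  if (!is.null(x$cutoff)) cat(" cutoff =", x$cutoff, x$units)
  cat("\n")
  invisible(x)
}

#' Turn raw values into a binary adversity indicator
#'
#' Applies an adversity rule to a numeric vector. Missing values propagate
#' (missing in, missing out); binarization never invents data.
#'
#' For `bottom_decile` the cutoff is the empirical 10th percentile of the
#' non-missing values (type-7 interpolation) and values *strictly below* it
#' are flagged, so a constant vector yields no adversity and at most 10% of
#' non-missing values can be flagged.
#'
#' @param values numeric vector in natural units (0/1 for `binary_as_is`).
#' @param rule an [adversity_rules] object.
#' @param cutoff optional override of the rule cutoff; used when re-deriving
#'   an indicator after a counterfactual shift, so the original cohort
#'   percentile (frozen at first derivation) keeps applying.
#' @return integer vector of 0/1/NA, same length as `values`.
#' @export
binarize_adversity <- function(values, rule, cutoff = NULL) {
  if (!inherits(rule, "adversity_rule")) stop("`rule` must be an adversity_rule")
  if (length(values) == 0L) stop("binarize_adversity: empty value vector")
  values <- as.numeric(values)
  out <- switch(
    rule$kind,
    binary_as_is = {
      bad <- !is.na(values) & !(values %in% c(0, 1))
      if (any(bad)) {
        stop("binarize_adversity: non-binary value(s) under binary_as_is rule: ",
             paste(utils::head(unique(values[bad]), 3L), collapse = ", "))
      }
      values
    },
    threshold_below = as.numeric(values < (cutoff %||% rule$cutoff)),
    threshold_above = as.numeric(values > (cutoff %||% rule$cutoff)),
    bottom_decile = {
      if (all(is.na(values))) stop("binarize_adversity: all values missing")
      cut <- cutoff %||%
        unname(stats::quantile(values, probs = 0.1, na.rm = TRUE, type = 7))
      as.numeric(values < cut)
    },
    stop("unknown adversity rule kind: ", rule$kind)
  )
  as.integer(out)
}

# cutoff actually used by a rule on a given vector (frozen for reuse)
rule_cutoff <- function(values, rule) {
  switch(rule$kind,
         binary_as_is = NA_real_,
         threshold_below = rule$cutoff,
         threshold_above = rule$cutoff,
         bottom_decile = unname(stats::quantile(values, probs = 0.1,
                                                na.rm = TRUE, type = 7)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
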