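#' Multiple imputation by chained equations
#'
#' Produces `M` completed copies of a table by iterated conditional
#' draws: each incomplete variable is regressed on all other variables in
#' the model set using the rows where it was observed, the model
#' parameters are perturbed by a posterior draw (so imputations differ
#' across the `M` chains), and its missing cells are replaced by draws
#' from the conditional model. Variables are visited in increasing order
#' of missingness for `cycles` full sweeps per chain.
#'
#' Conditional models: `"linear"` — ordinary least squares with the
#' standard Bayesian draw of the residual variance (scaled
#' inverse-chi-squared) and coefficients; `"logistic"` — IRLS fit with a
#' normal approximation draw of the coefficients and a Bernoulli draw of
#' the imputed value; `"ordinal"` — linear on the numeric codes, then
#' rounded to the nearest observed level (a deliberate simplification
#' that keeps the conditional-model zoo small); `"lognormal"` — linear
#' on the log scale, back-transformed, for strictly positive skewed
#' variables such as income. A conditional logistic
#' fit that fails to converge (e.g. separation in a sparse cell) falls
#' back to a ridge-stabilized fit and the event is logged on the result.
#'
#' Observed cells are preserved bit-exactly in every copy; identical
#' inputs and seed reproduce the imputation run exactly.
#'
#' @param table data.frame; columns not in `columns` (e.g. identifiers)
#'   are carried through untouched and never used as predictors.
#' @param variable_models optional named character vector mapping column
#'   name to `"linear"`, `"logistic"` or `"ordinal"`; unnamed columns are
#'   auto-typed (0/1 columns logistic, few-level integer codes ordinal,
#'   otherwise linear).
#' @param M number of imputed datasets (the study default is 50).
#' @param cycles chained-equation sweeps per dataset (default 10).
#' @param seed integer seed; each chain uses an independent sub-stream.
#' @param columns character vector of columns participating in the
#'   imputation model (predictors and imputation targets); defaults to
#'   every column except `participant_id`.
#' @return an `imputation_set`: `tables` (list of M completed
#'   data.frames), `M`, `cycles`, `seed`, `original_na` (logical matrix of
#'   the input missingness over `columns`), `models` (resolved model
#'   types), and `log` (fallback events).
#' @export
impute_chained <- function(table, variable_models = NULL, M = 50L,
                           cycles = 10L, seed = 1L, columns = NULL) {
  if (is.null(columns)) columns <- setdiff(names(table), "participant_id")
  missing_cols <- columns[vapply(table[columns], anyNA, logical(1))]
  fully_missing <- missing_cols[vapply(table[missing_cols],
                                       function(x) all(is.na(x)), logical(1))]
  if (length(fully_missing)) {
    stop("impute_chained: variable(s) 100% missing: ",
         paste(fully_missing, collapse = ", "))
  }
  if (length(setdiff(missing_cols, columns))) stop("unreachable")
  if (!length(setdiff(columns, missing_cols))) {
    stop("impute_chained: at least one fully observed column is required")
  }

  models <- resolve_variable_models(table, missing_cols, variable_models)
  na_mat <- as.matrix(is.na(table[columns]))
  colnames(na_mat) <- columns

  out <- list(tables = vector("list", M), M = as.integer(M),
              cycles = as.integer(cycles), seed = as.integer(seed),
              original_na = na_mat, models = models, log = character(0))
  class(out) <- "imputation_set"

  if (!length(missing_cols)) {
    out$tables <- rep(list(table), M)
    return(out)
  }

  # visit order: least missing first
  ord <- missing_cols[order(colSums(na_mat[, missing_cols, drop = FALSE]))]
  logs <- character(0)
  for (m in seq_len(M)) {
    res <- with_seed(derive_seed(seed, paste0("chain", m)),
                     impute_one_chain(table, columns, ord, models, na_mat, cycles))
    out$tables[[m]] <- res$table
    logs <- c(logs, res$log)
  }
  out$log <- logs
  out
}

resolve_variable_models <- function(table, missing_cols, variable_models) {
  vapply(missing_cols, function(v) {
    if (!is.null(variable_models) && v %in% names(variable_models)) {
      mod <- variable_models[[v]]
      if (!mod %in% c("linear", "logistic", "ordinal", "lognormal")) {
        stop("impute_chained: unknown model type '", mod, "' for ", v)
      }
      return(mod)
    }
    x <- table[[v]][!is.na(table[[v]])]
    u <- unique(x)
    if (all(u %in% c(0, 1))) return("logistic")
    if (all(u == round(u)) && length(u) <= 12) return("ordinal")
    "linear"
  }, character(1))
}

impute_one_chain <- function(table, columns, ord, models, na_mat, cycles) {
  log <- character(0)
  # initialize missing cells by resampling observed values
  for (v in ord) {
    na <- na_mat[, v]
    obs <- table[[v]][!na]
    table[[v]][na] <- sample(obs, sum(na), replace = TRUE)
  }
  for (cy in seq_len(cycles)) {
    for (v in ord) {
      na <- na_mat[, v]
      preds <- setdiff(columns, v)
      X <- cbind(`(Intercept)` = 1,
                 as.matrix(as.data.frame(lapply(table[preds], as.numeric))))
      y <- as.numeric(table[[v]])
      drawn <- switch(
        models[[v]],
        linear = draw_linear(X, y, na),
        lognormal = {
          d <- draw_linear(X, log(y), na)
          list(values = exp(d$values), log = d$log)
        },
        ordinal = {
          lv <- sort(unique(y[!na_mat[, v]]))
          d <- draw_linear(X, y, na)
          list(values = lv[pmax(1L, pmin(length(lv),
                 sapply(d$values, function(z) which.min(abs(lv - z)))))],
               log = d$log)
        },
        logistic = draw_logistic(X, y, na))
      table[[v]][na] <- drawn$values
      if (length(drawn$log)) log <- c(log, paste0(v, " cycle ", cy, ": ", drawn$log))
    }
  }
  list(table = table, log = log)
}

# Bayesian-draw linear imputation: sigma^2 from scaled inverse-chi-square,
# beta from its normal posterior, values from the predictive normal
draw_linear <- function(X, y, na) {
  Xo <- X[!na, , drop = FALSE]
  yo <- y[!na]
  qr_ <- qr(Xo)
  keep <- qr_$pivot[seq_len(qr_$rank)]
  Xo <- Xo[, keep, drop = FALSE]
  bhat <- qr.coef(qr(Xo), yo)
  res <- yo - drop(Xo %*% bhat)
  df <- max(length(yo) - ncol(Xo), 1L)
  sigma2 <- sum(res^2) / stats::rchisq(1L, df)
  XtX <- crossprod(Xo)
  R <- tryCatch(chol(XtX), error = function(e) chol(XtX + diag(1e-8 * max(diag(XtX)), ncol(XtX))))
  # beta ~ N(bhat, sigma2 * (X'X)^-1) via backsolve of the Cholesky factor
  beta <- bhat + sqrt(sigma2) * backsolve(R, stats::rnorm(ncol(Xo)))
  Xm <- X[na, keep, drop = FALSE]
  list(values = drop(Xm %*% beta) + stats::rnorm(sum(na), 0, sqrt(sigma2)),
       log = character(0))
}

draw_logistic <- function(X, y, na) {
  Xo <- X[!na, , drop = FALSE]
  yo <- y[!na]
  keep <- qr(Xo)$pivot[seq_len(qr(Xo)$rank)]
  Xo <- Xo[, keep, drop = FALSE]
  log <- character(0)
  fit <- suppressWarnings(fit_logistic_mle(Xo, yo, max_iter = 50L, tol = 1e-8))
  if (!fit$converged || fit$separation) {
    fit <- fit_logistic_mle(Xo, yo, ridge = 0.1, max_iter = 50L, tol = 1e-8)
    log <- "non-convergent conditional fit; ridge-stabilized fallback"
  }
  R <- tryCatch(chol(fit$vcov), error = function(e)
    chol(fit$vcov + diag(1e-10, ncol(fit$vcov))))
  beta <- fit$coefficients + drop(crossprod(R, stats::rnorm(length(fit$coefficients))))
  p <- stats::plogis(drop(X[na, keep, drop = FALSE] %*% beta))
  list(values = stats::rbinom(sum(na), 1L, p), log = log)
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("<imputation_set> M =", x$M, "| cycles =", x$cycles,
      "| seed =", x$seed, "\n")
  miss <- colSums(x$original_na)
  miss <- miss[miss > 0]
  cat("  incomplete variables:", length(miss), "| missing cells:", sum(miss), "\n")
  if (length(x$dropped_rows)) cat("  analysis rows dropped:", length(x$dropped_rows), "\n")
  invisible(x)
}

#' Delete rows whose outcome was originally missing
#'
#' The outcome participates in the imputation models (it is a predictor
#' for every incomplete covariate), but imputed outcome values are not
#' analysed: rows where any named outcome column was missing in the
#' original data are removed from every completed table
#' (multiple-imputation-then-deletion). Deletion depends only on the
#' original missingness pattern, so the same rows go in all M copies.
#'
#' @param imputation_set result of [impute_chained()].
#' @param outcome_columns character vector of outcome column names.
#' @return the `imputation_set` with filtered tables and a
#'   `dropped_rows` field (row indices of the input table).
#' @export
drop_imputed_outcomes <- function(imputation_set, outcome_columns) {
  na_mat <- imputation_set$original_na
  outcome_columns <- intersect(outcome_columns, colnames(na_mat))
  drop <- if (length(outcome_columns)) {
    which(rowSums(na_mat[, outcome_columns, drop = FALSE]) > 0)
  } else {
    integer(0)
  }
  if (length(drop)) {
    imputation_set$tables <- lapply(imputation_set$tables, function(t) {
      out <- t[-drop, , drop = FALSE]
      rownames(out) <- NULL
      out
    })
  }
  imputation_set$dropped_rows <- drop
  imputation_set
}

#' Pool estimates across imputations by Rubin's rules
#'
#' The pooled point estimate is the mean of the per-imputation estimates;
#' the total variance combines the mean within-imputation variance `W`
#' and the between-imputation variance `B` as `T = W + (1 + 1/M) B`.
#' Confidence intervals use a t reference with the Rubin degrees of
#' freedom `nu = (M - 1) (1 + W / ((1 + 1/M) B))^2`; when `B = 0` (all
#' estimates identical) the reference is normal. Pooling is always done
#' on the estimation scale (log-odds, log risk ratios), never on the
#' exponentiated scale.
#'
#' @param estimates numeric vector of M point estimates.
#' @param variances numeric vector of M squared standard errors.
#' @param conf confidence level (default 0.95).
#' @return list with `estimate`, `W`, `B`, `T`, `se`, `df`, `ci_low`,
#'   `ci_high`, `M`.
#' @export
pool_rubin <- function(estimates, variances, conf = 0.95) {
  M <- length(estimates)
  if (M < 2L) stop("pool_rubin: at least 2 imputations required")
  if (length(variances) != M) stop("pool_rubin: length mismatch")
  est <- mean(estimates)
  W <- mean(variances)
  B <- stats::var(estimates)
  Tt <- W + (1 + 1 / M) * B
  se <- sqrt(Tt)
  if (B <= 0) {
    df <- Inf
    q <- stats::qnorm(1 - (1 - conf) / 2)
  } else {
    df <- (M - 1) * (1 + W / ((1 + 1 / M) * B))^2
    q <- stats::qt(1 - (1 - conf) / 2, df)
  }
  list(estimate = est, W = W, B = B, T = Tt, se = se, df = df,
       ci_low = est - q * se, ci_high = est + q * se, M = M)
}
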