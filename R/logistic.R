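#' Maximum-likelihood logistic regression by IRLS
#'
#' Fits a binary logistic model by iteratively reweighted least squares
#' with step-halving, iterating until the relative change in
#' log-likelihood falls below `tol` (default 1e-10) or `max_iter`
#' iterations. The Wald covariance is the inverse of the observed
#' information at the optimum. Complete or quasi-complete separation is
#' detected as a coefficient diverging past `|beta| > 15` on the
#' log-odds scale and reported on the fit object (with a warning), never
#' silently returned as a converged estimate.
#'
#' @param X numeric design matrix including the intercept column.
#' @param y 0/1 outcome vector, no missing values.
#' @param ridge optional L2 penalty (per-coefficient, intercept included);
#'   `0` for plain maximum likelihood. The imputation engine uses a small
#'   ridge as a stabilizing fallback for ill-conditioned conditional fits.
#' @param max_iter,tol IRLS controls.
#' @return a `model_fit` object: `coefficients`, `vcov`, `converged`,
#'   `separation`, `loglik`, `iterations`, `n`.
#' @export
fit_logistic_mle <- function(X, y, ridge = 0, max_iter = 100L, tol = 1e-10) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (anyNA(X) || anyNA(y)) stop("fit_logistic_mle: missing cells in design or outcome")
  if (!all(y %in% c(0, 1))) stop("fit_logistic_mle: outcome must be 0/1")
  if (nrow(X) != length(y)) stop("fit_logistic_mle: row mismatch")
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))

  beta <- numeric(p)
  ll <- penalized_loglik(X, y, beta, ridge)
  converged <- FALSE
  separation <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    mu <- stats::plogis(drop(X %*% beta))
    w <- pmax(mu * (1 - mu), 1e-12)
    H <- crossprod(X, X * w)
    if (ridge > 0) H <- H + diag(ridge, p)
    g <- drop(crossprod(X, y - mu)) - ridge * beta
    step <- tryCatch(solve(H, g), error = function(e) {
      solve(H + diag(1e-8 * max(diag(H)), p), g)
    })
    # step-halving keeps the log-likelihood non-decreasing
    s <- 1
    repeat {
      cand <- beta + s * step
      ll_new <- penalized_loglik(X, y, cand, ridge)
      if (ll_new >= ll - 1e-12 || s < 1e-10) break
      s <- s / 2
    }
    rel <- abs(ll_new - ll) / (abs(ll) + 1e-300)
    beta <- cand
    ll <- ll_new
    if (any(abs(beta) > 15) && ridge == 0) {
      separation <- TRUE
      warning("fit_logistic_mle: coefficient diverging past |beta| > 15; ",
              "possible complete separation")
      break
    }
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  mu <- stats::plogis(drop(X %*% beta))
  w <- pmax(mu * (1 - mu), 1e-12)
  H <- crossprod(X, X * w)
  if (ridge > 0) H <- H + diag(ridge, p)
  V <- tryCatch(solve(H), error = function(e) {
    solve(H + diag(1e-8 * max(diag(H)), p))
  })
  dimnames(V) <- list(colnames(X), colnames(X))
  structure(list(coefficients = stats::setNames(drop(beta), colnames(X)),
                 vcov = V, converged = converged, separation = separation,
                 loglik = ll, iterations = iter, n = length(y)),
            class = "model_fit")
}

penalized_loglik <- function(X, y, beta, ridge) {
  eta <- drop(X %*% beta)
  # numerically stable Bernoulli log-likelihood
  ll <- sum(y * eta - log1p(exp(-abs(eta))) - pmax(eta, 0))
  if (ridge > 0) ll <- ll - ridge / 2 * sum(beta^2)
  ll
}

#' @export
print.model_fit <- function(x, ...) {
  cat("<model_fit> n =", x$n, "| logLik =", format(x$loglik, digits = 6),
      "| iterations =", x$iterations,
      if (!x$converged) "| NOT CONVERGED" else "",
      if (x$separation) "| SEPARATION DETECTED" else "", "\n")
  se <- sqrt(diag(x$vcov))
  print(round(cbind(estimate = x$coefficients, se = se,
                    or = exp(x$coefficients)), 4))
  invisible(x)
}

#' @export
coef.model_fit <- function(object, ...) object$coefficients

#' @export
vcov.model_fit <- function(object, ...) object$vcov

#' Predicted case probabilities from a fitted logistic model
#'
#' @param object a `model_fit`.
#' @param newdata design matrix with columns matching the fit's
#'   coefficients.
#' @param ... unused.
#' @return vector of probabilities.
#' @export
predict.model_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  X <- X[, names(object$coefficients), drop = FALSE]
  stats::plogis(drop(X %*% object$coefficients))
}
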