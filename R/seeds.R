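#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' All randomness in the package flows through named seed streams so that
#' stages (cohort generation, missingness, imputation chains, bootstrap,
#' intervention assignment) are independently reproducible from one master
#' seed. The derivation is a small multiplicative hash over the label,
#' guaranteed to stay inside the 32-bit range R accepts in [set.seed()].
#'
#' @param seed integer master seed.
#' @param stream character label naming the consumer of the sub-seed.
#' @return an integer in [0, 2^31 - 2], deterministic in (seed, stream).
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- abs(as.double(seed)) %% 2147483647
  for (k in utf8ToInt(as.character(stream))) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr under a local RNG state; the caller's stream is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# round half away from zero; used for sampled counts and integer projections
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)
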