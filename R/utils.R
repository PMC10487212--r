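# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so generators behave as pure functions of (config, seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Derive a reproducible per-stage seed from a root seed
#'
#' Each pipeline stage draws its randomness from a seed derived
#' deterministically from the root seed and the stage name, so any stage can
#' be replayed in isolation.
#'
#' @param root_seed integer root seed.
#' @param stage character stage name.
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(root_seed, stage) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L,
            is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(root_seed) + 10007 * h) %% (2^31 - 1))
}

# Quantile of a normal(mean, sd) truncated to [lo, hi].
qtruncnorm <- function(p, mean, sd, lo = -Inf, hi = Inf) {
  a <- stats::pnorm((lo - mean) / sd)
  b <- stats::pnorm((hi - mean) / sd)
  stats::qnorm(a + p * (b - a)) * sd + mean
}

# Pearson correlation that tolerates zero-variance inputs (returns NA).
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
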