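# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-stage child seeds derived from one root seed, so adding a
# stage never perturbs the draws of another.  Always < 2^31.
child_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Probabilities bounded away from {0,1} before taking logits / log-likelihoods.
.PROB_EPS <- 1e-6

is_binary01 <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x %in% c(0, 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

z_quantile <- function(level, z = NULL) {
  stopifnot(is.numeric(level), length(level) == 1L, level > 0, level < 1)
  if (!is.null(z)) {
    stopifnot(is.numeric(z), z > 0)
    return(z)
  }
  stats::qnorm((1 + level) / 2)
}
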