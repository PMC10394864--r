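# In-code fixtures: small cohorts with known structure.

# Discrete-covariate cohort (p binary covariates, <= 2^p strata) with
# mid-range cell probabilities so that no stratum-by-arm outcome mean sits
# at 0 or 1 (needed for exact nonparametric-MLE comparisons).
make_discrete_cohort <- function(n = 300, seed = 1, p = 2) {
  for (s in seed + 0:20) {
    ch <- with_test_seed(s, {
      w <- matrix(rbinom(n * p, 1, 0.5), n, p,
                  dimnames = list(NULL, paste0("w", seq_len(p))))
      ps <- plogis(-0.3 + 0.8 * w[, 1] - 0.5 * w[, min(2, p)])
      a <- rbinom(n, 1, ps)
      y <- rbinom(n, 1, plogis(-0.8 + 0.9 * a + 0.7 * w[, 1] +
                                 0.4 * w[, min(2, p)]))
      cohort(y = y, a = a, w = w)
    })
    if (all_cells_interior(ch)) return(ch)
  }
  stop("could not build a discrete cohort with interior cells")
}

all_cells_interior <- function(ch) {
  key <- apply(ch$w, 1, paste, collapse = "|")
  for (s in unique(key)) {
    for (arm in 0:1) {
      ys <- ch$y[key == s & ch$a == arm]
      if (length(ys) == 0 || mean(ys) %in% c(0, 1)) return(FALSE)
    }
  }
  TRUE
}

# Saturated (fully stratified) nuisance fits: the nonparametric MLE on a
# discrete covariate space.
saturated_nuisances <- function(ch, bound = 1e-3, truncate = FALSE) {
  key <- apply(ch$w, 1, paste, collapse = "|")
  q1 <- q0 <- g <- numeric(ch$n)
  for (s in unique(key)) {
    idx <- key == s
    q1[idx] <- mean(ch$y[idx & ch$a == 1])
    q0[idx] <- mean(ch$y[idx & ch$a == 0])
    g[idx] <- mean(ch$a[idx])
  }
  qbar <- ifelse(ch$a == 1, q1, q0)
  tlroadmap:::nuisance_fits(qbar, q1, q0, g, bound = bound,
                            truncate = truncate)
}

# run code under a seed without clobbering the suite's RNG stream
with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# fast analysis configuration used where the learner library is not itself
# under test
fast_config <- function(seed = 1, ...) {
  run_config(v_folds = 10, outcome_library = "logistic",
             ps_library = "logistic", seed = seed, ...)
}
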