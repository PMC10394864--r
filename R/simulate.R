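#' Default covariate specification for the synthetic cohort
#'
#' Ten baseline covariates emulating the adjustment set of the motivating
#' twin-pregnancy cohort: maternal age (discretized normal), height and
#' weight (correlated normals), BMI derived from them, an obesity indicator
#' (BMI >= 25), and five Bernoulli indicators (first pregnancy, single
#' placenta, assistive reproductive technology use, magnesium
#' administration, corticosteroid administration).  Distributional choices
#' are conventional for this population and are overridable; they are not a
#' calibration to any real data set.
#'
#' @return A list of covariate specs, each `list(name, family, params)`.
#'   Supported families: `"normal"` (params `mean`, `sd`, optional `round`,
#'   `lo`, `hi`), `"normal_corr"` (adds `rho`, `with`), `"bernoulli"`
#'   (`p`), `"bmi"` (`height`, `weight` column names), `"indicator"`
#'   (`var`, `threshold`).
#' @export
default_covariate_spec <- function() {
  list(
    list(name = "age", family = "normal",
         params = list(mean = 31, sd = 4.8, round = 0, lo = 16, hi = 48)),
    list(name = "height", family = "normal",
         params = list(mean = 158, sd = 5.5, round = 1)),
    list(name = "weight", family = "normal_corr",
         params = list(mean = 55, sd = 8, rho = 0.4, with = "height",
                       round = 1)),
    list(name = "bmi", family = "bmi",
         params = list(height = "height", weight = "weight")),
    list(name = "obesity", family = "indicator",
         params = list(var = "bmi", threshold = 25)),
    list(name = "primipara", family = "bernoulli", params = list(p = 0.55)),
    list(name = "single_placenta", family = "bernoulli",
         params = list(p = 0.30)),
    list(name = "art", family = "bernoulli", params = list(p = 0.35)),
    list(name = "magnesium", family = "bernoulli", params = list(p = 0.25)),
    list(name = "corticosteroid", family = "bernoulli",
         params = list(p = 0.40))
  )
}

#' Simulation configuration for synthetic cohorts
#'
#' Defines the data-generating process the roadmap is tested against: a
#' covariate specification, logistic models for treatment assignment and the
#' outcome, an optional structurally untreated (contra-indicated) stratum, an
#' optional unmeasured binary confounder `U` entering both linear predictors,
#' and an optional total-dose model with per-group event-rate targets.
#'
#' The default coefficients were fixed once to emulate the structure of the
#' motivating cohort: n = 225, roughly a third of subjects treated with
#' moderate propensity discrimination, a rare-ish outcome, and a true
#' marginal risk difference near 0.21.
#'
#' @param n cohort size.
#' @param covariates covariate spec, see [default_covariate_spec()].
#' @param propensity `list(intercept, coef)`; `coef` a named numeric vector
#'   over covariate names for logit P(A = 1 | W).
#' @param outcome `list(intercept, treatment, coef)` for
#'   logit P(Y = 1 | A, W); `treatment` is the coefficient on `A`.
#' @param contraindication_fraction fraction in \[0, 1) of subjects placed in
#'   a stratum with structurally zero treatment probability; exactly
#'   `floor(fraction * n)` subjects are assigned to it.
#' @param contraindication_outcome_shift additive log-odds effect of the
#'   contra-indicated stratum on the outcome (0 = stratum affects treatment
#'   only).
#' @param confounder_strength log-odds effect of a hidden Bernoulli `U` on
#'   treatment assignment.
#' @param confounder_outcome_strength log-odds effect of `U` on the outcome;
#'   defaults to `confounder_strength`.
#' @param confounder_prevalence P(U = 1).
#' @param dose optional list with `group_event_rates` (length 7, event
#'   probability per dose group 0..6), `group_probs` (length 6, distribution
#'   of treated subjects over positive dose groups) and `breaks` (7 values,
#'   group boundaries on the 72 mg/24 h scale).
#' @param seed root RNG seed; per-stage child streams are derived from it so
#'   that, e.g., adding covariates does not perturb treatment draws.
#' @return An object of class `tl_sim_config`.
#' @export
sim_config <- function(n = 225,
                       covariates = default_covariate_spec(),
                       propensity = list(
                         intercept = -2.20,
                         coef = c(age = 0.06, bmi = -0.05, primipara = 0.55,
                                  single_placenta = 0.40, art = -0.45,
                                  magnesium = 1.00, corticosteroid = 0.70)),
                       outcome = list(
                         intercept = -5.80,
                         treatment = 1.90,
                         coef = c(age = 0.03, bmi = 0.07, magnesium = 0.60,
                                  corticosteroid = 0.40,
                                  single_placenta = 0.30)),
                       contraindication_fraction = 0,
                       contraindication_outcome_shift = 0,
                       confounder_strength = 0,
                       confounder_outcome_strength = NULL,
                       confounder_prevalence = 0.5,
                       dose = NULL,
                       seed = 1L) {
  stopifnot(n >= 1,
            contraindication_fraction >= 0, contraindication_fraction < 1,
            confounder_prevalence > 0, confounder_prevalence < 1)
  if (is.null(confounder_outcome_strength)) {
    confounder_outcome_strength <- confounder_strength
  }
  if (!is.null(dose)) {
    dose$group_probs <- dose$group_probs %||% rep(1 / 6, 6)
    dose$breaks <- dose$breaks %||% c(0, 10, 20, 30, 40, 50, 80)
    stopifnot(length(dose$group_event_rates) == 7,
              length(dose$group_probs) == 6,
              length(dose$breaks) == 7)
    if (any(dose$group_event_rates <= 0) || any(dose$group_event_rates >= 1)) {
      stop("dose group event-rate targets must lie in (0, 1)", call. = FALSE)
    }
  }
  structure(
    list(n = as.integer(n), covariates = covariates,
         propensity = propensity, outcome = outcome,
         contraindication_fraction = contraindication_fraction,
         contraindication_outcome_shift = contraindication_outcome_shift,
         confounder_strength = confounder_strength,
         confounder_outcome_strength = confounder_outcome_strength,
         confounder_prevalence = confounder_prevalence,
         dose = dose, seed = as.integer(seed)),
    class = "tl_sim_config"
  )
}

# Draw an n x p covariate matrix from a covariate spec (RNG state: caller's).
draw_covariates <- function(spec, n) {
  w <- matrix(NA_real_, n, length(spec),
              dimnames = list(NULL, vapply(spec, `[[`, "", "name")))
  for (s in spec) {
    p <- s$params
    x <- switch(s$family,
      normal = stats::rnorm(n, p$mean, p$sd),
      normal_corr = {
        base <- w[, p$with]
        zb <- (base - mean(base)) / max(stats::sd(base), 1e-12)
        p$mean + p$sd * (p$rho * zb + sqrt(1 - p$rho^2) * stats::rnorm(n))
      },
      bernoulli = stats::rbinom(n, 1, p$p),
      bmi = w[, p$weight] / (w[, p$height] / 100)^2,
      indicator = as.numeric(w[, p$var] >= p$threshold),
      stop("unknown covariate family: ", s$family, call. = FALSE)
    )
    if (!is.null(p$round)) x <- round(x, p$round)
    if (!is.null(p$lo)) x <- clip(x, p$lo, p$hi)
    if (s$family == "bmi") x <- round(x, 1)
    w[, s$name] <- x
  }
  w
}

lin_pred <- function(intercept, coef, w) {
  lp <- rep(intercept, nrow(w))
  if (length(coef)) {
    absent <- setdiff(names(coef), colnames(w))
    if (length(absent)) {
      stop("coefficient names not among covariates: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    lp <- lp + drop(w[, names(coef), drop = FALSE] %*% coef)
  }
  lp
}

# Hidden-structure helpers: U (unmeasured confounder) and C (contra-indicated
# stratum) are never part of the emitted covariate matrix.
prob_treat <- function(config, w, u, cc) {
  p <- stats::plogis(lin_pred(config$propensity$intercept,
                              config$propensity$coef, w) +
                       config$confounder_strength * u)
  p[cc == 1] <- 0
  p
}

prob_outcome <- function(config, a, w, u, cc) {
  stats::plogis(lin_pred(config$outcome$intercept, config$outcome$coef, w) +
                  config$outcome$treatment * a +
                  config$confounder_outcome_strength * u +
                  config$contraindication_outcome_shift * cc)
}

#' Generate a synthetic cohort with known counterfactual truth
#'
#' Draws covariates, hidden structure (unmeasured confounder and
#' contra-indicated stratum), treatment, and outcome from the configured
#' data-generating process, and pairs the cohort with the simulation truth
#' computed by [true_effect_oracle()] on the same configuration.
#'
#' @param config a [sim_config()].
#' @param truth_mc_size Monte-Carlo size for the truth computation.
#' @return A list with elements `cohort` (a validated [cohort()]), `truth`
#'   (class `tl_sim_truth`: `psi1`, `psi0`, `rd`, `psi_stat`, `delta`,
#'   `mc_se`), `warnings` (character; e.g. degenerate arm sizes) and
#'   `hidden` (the latent confounder and contra-indication indicators, for
#'   auditing — never part of the emitted cohort).
#' @export
generate_cohort <- function(config, truth_mc_size = 1e5) {
  stopifnot(inherits(config, "tl_sim_config"))
  seeds <- child_seeds(config$seed, 6L)
  n <- config$n
  w <- with_seed(seeds[1], draw_covariates(config$covariates, n))
  hid <- with_seed(seeds[2], {
    u <- stats::rbinom(n, 1, config$confounder_prevalence)
    m <- floor(config$contraindication_fraction * n)
    cc <- integer(n)
    if (m > 0) cc[sample.int(n, m)] <- 1L
    list(u = u, cc = cc)
  })
  ps <- prob_treat(config, w, hid$u, hid$cc)
  a <- with_seed(seeds[3], stats::rbinom(n, 1, ps))
  y <- with_seed(seeds[4],
                 stats::rbinom(n, 1, prob_outcome(config, a, w, hid$u,
                                                  hid$cc)))
  warnings <- character()
  if (sum(a) < 2 || sum(1 - a) < 2) {
    warnings <- c(warnings,
                  sprintf("degenerate treatment split: %d treated of %d",
                          sum(a), n))
  }
  if (sum(y) == 0) warnings <- c(warnings, "no outcome events generated")
  dose <- NULL
  if (!is.null(config$dose)) {
    dose <- with_seed(seeds[5], draw_doses(config, a))
  }
  ch <- cohort(y = y, a = a, w = w, dose = dose)
  truth <- true_effect_oracle(config, mc_size = truth_mc_size,
                              seed = seeds[6])
  list(cohort = ch, truth = truth, warnings = warnings,
       hidden = list(u = hid$u, contraindicated = hid$cc))
}

draw_doses <- function(config, a) {
  br <- config$dose$breaks
  grp <- sample(1:6, sum(a), replace = TRUE, prob = config$dose$group_probs)
  d <- numeric(length(a))
  lo <- br[grp]
  hi <- br[grp + 1]
  d[a == 1] <- lo + stats::runif(sum(a)) * (hi - lo)
  d[a == 1] <- pmax(d[a == 1], 1e-6)  # group 1 doses must be strictly > 0
  d
}

#' Monte-Carlo oracle for the simulation truth
#'
#' Independently of any estimator, computes the counterfactual means
#' `E[Y1]`, `E[Y0]` by simulating outcomes under forced treatment and forced
#' control for the same covariate and hidden-structure draws, plus the
#' W-adjusted statistical estimand `psi_stat = E[E(Y|A=1,W) - E(Y|A=0,W)]`
#' obtained by marginalizing the hidden structure analytically within each
#' draw.  The injected causal gap is `delta = psi_stat - rd`; it is exactly 0
#' when no hidden structure is configured.
#'
#' @param config a [sim_config()].
#' @param mc_size number of Monte-Carlo draws (>= 1e4).
#' @param seed RNG seed for the oracle draws.
#' @return A `tl_sim_truth` list: `psi1`, `psi0`, `rd`, `psi_stat`, `delta`,
#'   `mc_se` (Monte-Carlo standard error of `rd`).
#' @export
true_effect_oracle <- function(config, mc_size = 1e5, seed = config$seed) {
  stopifnot(inherits(config, "tl_sim_config"), mc_size >= 1e4)
  with_seed(seed, {
    m <- as.integer(mc_size)
    w <- draw_covariates(config$covariates, m)
    u <- stats::rbinom(m, 1, config$confounder_prevalence)
    f <- config$contraindication_fraction
    cc <- stats::rbinom(m, 1, f)
    m1 <- prob_outcome(config, 1, w, u, cc)
    m0 <- prob_outcome(config, 0, w, u, cc)
    y1 <- stats::rbinom(m, 1, m1)
    y0 <- stats::rbinom(m, 1, m0)
    psi1 <- mean(y1)
    psi0 <- mean(y0)
    rd <- psi1 - psi0
    mc_se <- stats::sd(y1 - y0) / sqrt(m)

    hidden <- config$confounder_strength != 0 ||
      config$confounder_outcome_strength != 0 || f > 0
    if (!hidden) {
      psi_stat <- mean(m1 - m0)
      delta <- 0
    } else {
      # E(Y | A = a, W): mixture over the hidden (U, C) joint, which is
      # independent of W a priori but tilted by conditioning on A.
      pu <- config$confounder_prevalence
      states <- expand.grid(u = c(0, 1), cc = c(0, 1))
      states <- states[(f > 0) | states$cc == 0, , drop = FALSE]
      num1 <- num0 <- den1 <- den0 <- numeric(m)
      for (k in seq_len(nrow(states))) {
        uu <- states$u[k]; cck <- states$cc[k]
        ph <- (if (uu == 1) pu else 1 - pu) *
          (if (f > 0) (if (cck == 1) f else 1 - f) else 1)
        pa1 <- prob_treat(config, w, rep(uu, m), rep(cck, m))
        mm1 <- prob_outcome(config, 1, w, rep(uu, m), rep(cck, m))
        mm0 <- prob_outcome(config, 0, w, rep(uu, m), rep(cck, m))
        num1 <- num1 + ph * pa1 * mm1
        den1 <- den1 + ph * pa1
        num0 <- num0 + ph * (1 - pa1) * mm0
        den0 <- den0 + ph * (1 - pa1)
      }
      ok <- den1 > 0 & den0 > 0
      psi_stat <- mean(num1[ok] / den1[ok] - num0[ok] / den0[ok])
      # gap against the analytic causal mean of the same draws, so that MC
      # noise in the Bernoulli outcome draws does not leak into delta
      delta <- psi_stat - mean(m1 - m0)
    }
    structure(list(psi1 = psi1, psi0 = psi0, rd = rd,
                   psi_stat = psi_stat, delta = delta, mc_se = mc_se),
              class = "tl_sim_truth")
  })
}

#' @export
print.tl_sim_truth <- function(x, ...) {
  cat(sprintf(
    "<tl_sim_truth> E[Y1] = %.4f, E[Y0] = %.4f, true RD = %.4f (MC se %.1e)\n",
    x$psi1, x$psi0, x$rd, x$mc_se))
  cat(sprintf("  W-adjusted estimand = %.4f, causal gap delta = %.4f\n",
              x$psi_stat, x$delta))
  invisible(x)
}

#' Generate a cohort with a total-dose variable and targeted crude pattern
#'
#' For reconstructing the crude dose-response display: treated subjects
#' receive positive doses spread over the six positive dose groups, and the
#' outcome is drawn per group at the configured event-rate target, so the
#' crude proportions approximate the configured (typically non-monotonic)
#' pattern.  Untreated subjects have dose exactly 0.
#'
#' @param config a [sim_config()] whose `dose` block is present.
#' @return A validated [cohort()] with a `dose` column; groups left empty by
#'   sampling are recorded in the `"empty_groups"` attribute.
#' @export
generate_dose_cohort <- function(config) {
  stopifnot(inherits(config, "tl_sim_config"))
  if (is.null(config$dose)) {
    stop("config has no dose model; set `dose` in sim_config()",
         call. = FALSE)
  }
  seeds <- child_seeds(config$seed, 6L)
  n <- config$n
  w <- with_seed(seeds[1], draw_covariates(config$covariates, n))
  hid <- with_seed(seeds[2], {
    u <- stats::rbinom(n, 1, config$confounder_prevalence)
    m <- floor(config$contraindication_fraction * n)
    cc <- integer(n)
    if (m > 0) cc[sample.int(n, m)] <- 1L
    list(u = u, cc = cc)
  })
  a <- with_seed(seeds[3],
                 stats::rbinom(n, 1, prob_treat(config, w, hid$u, hid$cc)))
  dose <- with_seed(seeds[5], draw_doses(config, a))
  grp <- dose_group(dose, config$dose$breaks[-7])
  y <- with_seed(seeds[4],
                 stats::rbinom(n, 1, config$dose$group_event_rates[grp + 1]))
  ch <- cohort(y = y, a = a, w = w, dose = dose)
  attr(ch, "empty_groups") <- setdiff(0:6, unique(grp))
  ch
}
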