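#' Fit outcome-regression and propensity-score nuisances by super learning
#'
#' The outcome regression \eqn{\bar Q(A, W) = E(Y | A, W)} is fit on the
#' covariates plus the treatment indicator; counterfactual predictions
#' \eqn{\bar Q(1, W)} and \eqn{\bar Q(0, W)} are obtained by setting the
#' treatment column to 1 and 0.  The propensity score
#' \eqn{g(W) = P(A = 1 | W)} is fit on the covariates alone and truncated
#' two-sided to `[bound, 1 - bound]` with the bound from
#' [resolve_ps_bound()].
#'
#' @param cohort a validated [cohort()].
#' @param config a [run_config()].
#' @return A `tl_nuisance_fits` list: `qbar`, `q1`, `q0`, `g`, `g_trunc`,
#'   `bound`, plus the two `tl_super_learner` fits.
#' @export
fit_nuisances <- function(cohort, config) {
  stopifnot(inherits(cohort, "tl_cohort"), inherits(config, "tl_run_config"))
  if (sum(cohort$a) == 0 || sum(1 - cohort$a) == 0) {
    stop("positivity violated globally: one treatment arm is empty",
         call. = FALSE)
  }
  v <- min(config$v_folds, cohort$n)
  seeds <- child_seeds(config$seed, 2L)
  xq <- cbind(cohort$w, a = cohort$a)
  sl_q <- fit_super_learner(xq, cohort$y,
                            specs = config$outcome_library,
                            v = v, seed = seeds[1])
  x1 <- xq; x1[, "a"] <- 1
  x0 <- xq; x0[, "a"] <- 0
  sl_g <- fit_super_learner(cohort$w, cohort$a,
                            specs = config$ps_library,
                            v = v, seed = seeds[2])
  bound <- resolve_ps_bound(cohort$n, config$ps_bound)
  g <- predict_proba(sl_g, cohort$w)
  structure(
    list(qbar = predict_proba(sl_q, xq),
         q1 = predict_proba(sl_q, x1),
         q0 = predict_proba(sl_q, x0),
         g = g,
         g_trunc = clip(g, bound, 1 - bound),
         bound = bound,
         sl_outcome = sl_q, sl_ps = sl_g),
    class = "tl_nuisance_fits")
}

# Assemble a tl_nuisance_fits from externally supplied predictions.  Used by
# the targeting step directly and by tests that feed saturated
# (nonparametric-MLE) fits.
nuisance_fits <- function(qbar, q1, q0, g, bound = 0.001,
                          truncate = TRUE) {
  stopifnot(all(qbar > 0 & qbar < 1), all(g > 0 & g < 1))
  structure(
    list(qbar = qbar, q1 = q1, q0 = q0, g = g,
         g_trunc = if (truncate) clip(g, bound, 1 - bound) else g,
         bound = bound, sl_outcome = NULL, sl_ps = NULL),
    class = "tl_nuisance_fits")
}

clever_covariate <- function(a, g) {
  a / g - (1 - a) / (1 - g)
}

#' Targeting step: one-parameter logistic fluctuation
#'
#' Updates the initial outcome regression along the least-favorable
#' submodel for the average treatment effect:
#' \eqn{logit \bar Q^*(A, W) = logit \bar Q(A, W) + \epsilon H(A, W)} with
#' the signed clever covariate
#' \eqn{H(A, W) = A / g(W) - (1 - A) / (1 - g(W))} (truncated `g`).
#' \eqn{\epsilon} is fit by maximum likelihood (Newton iterations on the
#' offset-logistic score, tolerance 1e-12, at most 100 steps), after which
#' the efficient-influence-function estimating equation for the risk
#' difference is solved: the mean influence-curve value is numerically zero.
#'
#' @param nuisances a `tl_nuisance_fits`.
#' @param cohort the cohort the fits came from.
#' @return The nuisance list with updated `qbar`, `q1`, `q0` and an
#'   `epsilon` element.
#' @export
fluctuate <- function(nuisances, cohort) {
  stopifnot(inherits(nuisances, "tl_nuisance_fits"),
            inherits(cohort, "tl_cohort"))
  y <- cohort$y
  a <- cohort$a
  g <- nuisances$g_trunc
  h <- clever_covariate(a, g)
  off <- stats::qlogis(clip(nuisances$qbar, .PROB_EPS, 1 - .PROB_EPS))
  eps <- 0
  for (it in seq_len(100L)) {
    q <- stats::plogis(off + eps * h)
    score <- sum(h * (y - q))
    info <- sum(h^2 * q * (1 - q))
    if (info <= 0) break
    step <- score / info
    eps <- eps + step
    if (abs(step) < 1e-12 && abs(score) / length(y) < 1e-12) break
  }
  q <- stats::plogis(off + eps * h)
  if (abs(sum(h * (y - q))) / length(y) > 1e-9) {
    stop(sprintf(
      "fluctuation MLE did not converge (mean score %.2e after %d iterations)",
      sum(h * (y - q)) / length(y), it), call. = FALSE)
  }
  off1 <- stats::qlogis(clip(nuisances$q1, .PROB_EPS, 1 - .PROB_EPS))
  off0 <- stats::qlogis(clip(nuisances$q0, .PROB_EPS, 1 - .PROB_EPS))
  nuisances$qbar <- q
  nuisances$q1 <- stats::plogis(off1 + eps / g)        # H(1, W) = 1/g
  nuisances$q0 <- stats::plogis(off0 - eps / (1 - g))  # H(0, W) = -1/(1-g)
  nuisances$epsilon <- eps
  nuisances
}

#' Targeted estimate of the point-treatment effect
#'
#' Runs the full TMLE: super-learner nuisance fits, logistic fluctuation,
#' plug-in evaluation of the targeted arm means, and influence-curve
#' inference on the requested scale.  For the risk difference the
#' per-subject influence curve is
#' \deqn{IC_i = H(A_i, W_i)(Y_i - \bar Q^*(A_i, W_i)) + \bar Q^*(1, W_i) -
#'   \bar Q^*(0, W_i) - \hat\psi,}
#' with \eqn{\hat\sigma = sd(IC)/\sqrt{n}} and a Wald interval.  Risk-ratio
#' and odds-ratio contrasts are delta-method transforms of the targeted arm
#' means with intervals built on the log scale.
#'
#' @param cohort a validated [cohort()].
#' @param config a [run_config()].
#' @param nuisances optionally, precomputed (possibly saturated)
#'   `tl_nuisance_fits` to target instead of fitting by super learning.
#' @return A `tl_tmle_result`: `psi1`, `psi0`, `estimate`, `se`, `ci`,
#'   `ic` (risk-difference influence-curve values), `ic1`/`ic0` (arm-mean
#'   curves), `epsilon`, `scale`, `level`, `bound`, and the nuisance fits.
#' @export
tmle_estimate <- function(cohort, config = run_config(),
                          nuisances = NULL) {
  stopifnot(inherits(cohort, "tl_cohort"))
  if (is.null(nuisances)) nuisances <- fit_nuisances(cohort, config)
  targeted <- fluctuate(nuisances, cohort)
  y <- cohort$y
  a <- cohort$a
  n <- cohort$n
  g <- targeted$g_trunc
  psi1 <- mean(targeted$q1)
  psi0 <- mean(targeted$q0)
  rd <- psi1 - psi0
  ic1 <- (a / g) * (y - targeted$qbar) + targeted$q1 - psi1
  ic0 <- ((1 - a) / (1 - g)) * (y - targeted$qbar) + targeted$q0 - psi0
  ic <- ic1 - ic0
  eff <- effect_on_scale(psi1, psi0, ic1, ic0, scale = config$scale,
                         level = config$level)
  structure(
    list(psi1 = psi1, psi0 = psi0,
         rd = rd,
         estimate = eff$estimate, se = eff$se, ci = eff$ci,
         se_rd = stats::sd(ic) / sqrt(n),
         ci_rd = wald_ci(rd, stats::sd(ic) / sqrt(n), config$level),
         ic = ic, ic1 = ic1, ic0 = ic0,
         epsilon = targeted$epsilon,
         scale = config$scale, level = config$level,
         bound = targeted$bound,
         nuisances = targeted),
    class = "tl_tmle_result")
}

#' @export
print.tl_tmle_result <- function(x, ...) {
  cat(sprintf("<tl_tmle_result> scale %s\n", x$scale))
  cat(sprintf("  targeted arm means: E[Y1] = %.4f, E[Y0] = %.4f\n",
              x$psi1, x$psi0))
  cat(sprintf("  estimate = %.4f (se %.4f), %d%% CI [%.4f, %.4f]\n",
              x$estimate, x$se, round(100 * x$level),
              x$ci[1], x$ci[2]))
  cat(sprintf("  epsilon = %.3e, PS bound = %.4f, |mean IC| = %.2e\n",
              x$epsilon, x$bound, abs(mean(x$ic))))
  invisible(x)
}

#' Wald confidence interval
#'
#' @param psi point estimate.
#' @param sigma standard error (> 0).
#' @param level confidence level in (0, 1).
#' @param z optional fixed normal quantile (e.g. 1.96) overriding the exact
#'   quantile.
#' @return `c(lower, upper) = psi -/+ z * sigma`.
#' @examples
#' wald_ci(0.21, 0.062)  # c(0.0885, 0.3315) to 4 decimals
#' @export
wald_ci <- function(psi, sigma, level = 0.95, z = NULL) {
  if (!is.numeric(sigma) || sigma <= 0) {
    stop("`sigma` must be positive", call. = FALSE)
  }
  zq <- z_quantile(level, z)
  c(psi - zq * sigma, psi + zq * sigma)
}

#' Effect estimate and delta-method inference on a chosen scale
#'
#' Transforms the targeted arm means and their influence curves to the risk
#' difference, risk ratio, or odds ratio.  For RR/OR the standard error and
#' interval are computed on the log scale (influence curve of the log
#' contrast by the delta method) and the interval is exponentiated.
#'
#' @param psi1,psi0 targeted arm means.
#' @param ic1,ic0 influence-curve values of the two arm means.
#' @param scale `"RD"`, `"RR"`, or `"OR"`.
#' @param level confidence level.
#' @return List with `estimate`, `se` (on the estimation scale: identity for
#'   RD, log for RR/OR), `ci` (on the reporting scale), `log_estimate` for
#'   RR/OR.
#' @export
effect_on_scale <- function(psi1, psi0, ic1, ic0,
                            scale = c("RD", "RR", "OR"), level = 0.95) {
  scale <- match.arg(scale)
  n <- length(ic1)
  z <- z_quantile(level)
  if (scale == "RD") {
    est <- psi1 - psi0
    se <- stats::sd(ic1 - ic0) / sqrt(n)
    ci <- if (se > 0) wald_ci(est, se, level) else c(est, est)
    return(list(estimate = est, se = se, ci = ci))
  }
  if (psi0 <= 0 || psi0 >= 1 || psi1 <= 0 || psi1 >= 1) {
    stop("RR/OR require arm means strictly inside (0, 1)", call. = FALSE)
  }
  if (scale == "RR") {
    est <- psi1 / psi0
    ic_log <- ic1 / psi1 - ic0 / psi0
  } else {
    est <- (psi1 / (1 - psi1)) / (psi0 / (1 - psi0))
    ic_log <- ic1 / (psi1 * (1 - psi1)) - ic0 / (psi0 * (1 - psi0))
  }
  se_log <- stats::sd(ic_log) / sqrt(n)
  ci <- if (se_log > 0) exp(wald_ci(log(est), se_log, level)) else c(est, est)
  list(estimate = est, se = se_log, ci = ci, log_estimate = log(est))
}

#' Stratified g-computation oracle
#'
#' Brute-force plug-in for discrete covariates: within each covariate
#' stratum `w`, the treated and untreated outcome means are averaged with
#' stratum weights \eqn{\hat p(w)},
#' \eqn{\sum_w \hat p(w) [\bar y(1, w) - \bar y(0, w)]}.  Intended as an
#' independent check of the targeted estimator on small discrete problems;
#' it requires every stratum to contain both arms and errors (naming the
#' stratum) otherwise — the estimand is not identified from a stratum
#' without positivity.
#'
#' @param cohort a [cohort()] whose covariates take few distinct values.
#' @param max_strata safety cap on the number of distinct strata.
#' @return The stratified risk difference (a single number).
#' @export
gcomp_oracle <- function(cohort, max_strata = 32L) {
  stopifnot(inherits(cohort, "tl_cohort"))
  key <- apply(cohort$w, 1, paste, collapse = "|")
  strata <- unique(key)
  if (length(strata) > max_strata) {
    stop(sprintf("too many covariate strata (%d > %d) for the oracle",
                 length(strata), max_strata), call. = FALSE)
  }
  n <- cohort$n
  psi <- 0
  for (s in strata) {
    idx <- key == s
    a <- cohort$a[idx]
    if (sum(a) == 0 || sum(1 - a) == 0) {
      stop(sprintf(
        "positivity violated in stratum {%s}: %s subjects only", s,
        if (sum(a) == 0) "untreated" else "treated"), call. = FALSE)
    }
    y <- cohort$y[idx]
    psi <- psi + (sum(idx) / n) *
      (mean(y[a == 1]) - mean(y[a == 0]))
  }
  psi
}
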