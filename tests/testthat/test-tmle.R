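test_that("Wald intervals reproduce standard arithmetic", {
  ci <- wald_ci(0.21, 0.062)
  expect_equal(round(ci, 4), c(0.0885, 0.3315))
  expect_equal(round(ci, 2), c(0.09, 0.33))
  expect_equal(round(wald_ci(0, 1), 2), c(-1.96, 1.96))
  # 50% interval: half-width is the 75% normal quantile
  expect_equal(wald_ci(0, 1, level = 0.5)[2], qnorm(0.75))
  expect_equal(qnorm(0.75), 0.6745, tolerance = 1e-4)
  expect_error(wald_ci(0.2, 0), "positive")
})

test_that("propensity truncation clips exactly to [bound, 1 - bound]", {
  nf <- tlroadmap:::nuisance_fits(qbar = rep(0.3, 4), q1 = rep(0.4, 4),
                                  q0 = rep(0.2, 4),
                                  g = c(0.01, 0.5, 0.97, 0.06),
                                  bound = 0.06)
  expect_equal(nf$g_trunc, c(0.06, 0.5, 0.94, 0.06))
})

test_that("saturated nuisances need no fluctuation and match the g-computation oracle", {
  for (s in c(1, 7, 13)) {
    ch <- make_discrete_cohort(n = 300, seed = s)
    nf <- saturated_nuisances(ch)
    targeted <- fluctuate(nf, ch)
    expect_lt(abs(targeted$epsilon), 1e-6)
    fit <- tmle_estimate(ch, run_config(), nuisances = nf)
    expect_equal(fit$estimate, gcomp_oracle(ch), tolerance = 1e-6)
    expect_lt(abs(mean(fit$ic)), 1e-8)
  }
})

test_that("g-computation oracle matches hand arithmetic and guards positivity", {
  # single stratum: crude risk difference
  ch1 <- cohort(y = c(1, 0, 1, 0, 0, 0), a = c(1, 1, 1, 0, 0, 0),
                w = cbind(w = rep(1, 6)))
  expect_equal(gcomp_oracle(ch1), 2 / 3 - 0)

  # two strata, hand-computed: w=0 (4 subjects): ybar1 = 1, ybar0 = 1/2;
  # w=1 (4 subjects): ybar1 = 1/2, ybar0 = 0
  ch2 <- cohort(y = c(1, 1, 1, 0, 1, 0, 0, 0),
                a = c(1, 1, 0, 0, 1, 1, 0, 0),
                w = cbind(w = c(0, 0, 0, 0, 1, 1, 1, 1)))
  expect_equal(gcomp_oracle(ch2), 0.5 * (1 - 0.5) + 0.5 * (0.5 - 0))

  # empty treated cell in one stratum: error names the stratum
  ch3 <- cohort(y = c(0, 1, 0, 1), a = c(0, 0, 1, 0),
                w = cbind(w = c(0, 0, 1, 1)))
  expect_error(gcomp_oracle(ch3), "stratum \\{0\\}")
})

test_that("the fluctuation solves the estimating equation at any g scaling", {
  # a deliberately coarse Q (arm means, ignoring W) leaves a nonzero score,
  # so epsilon must move; rescaling g changes epsilon but the estimating
  # equation is solved either way
  ch <- make_discrete_cohort(n = 250, seed = 3)
  sat <- saturated_nuisances(ch)
  q1c <- rep(mean(ch$y[ch$a == 1]), ch$n)
  q0c <- rep(mean(ch$y[ch$a == 0]), ch$n)
  qc <- ifelse(ch$a == 1, q1c, q0c)
  nf <- tlroadmap:::nuisance_fits(qc, q1c, q0c, sat$g, bound = 0.001)
  nf_dist <- tlroadmap:::nuisance_fits(qc, q1c, q0c,
                                       pmin(pmax(sat$g * 0.6, 0.02), 0.98),
                                       bound = 0.001)
  t1 <- fluctuate(nf, ch)
  t2 <- fluctuate(nf_dist, ch)
  expect_gt(abs(t1$epsilon), 1e-8)
  expect_gt(abs(t2$epsilon - t1$epsilon), 1e-8)
  for (tt in list(t1, t2)) {
    h <- ch$a / tt$g_trunc - (1 - ch$a) / (1 - tt$g_trunc)
    expect_lt(abs(mean(h * (ch$y - tt$qbar))), 1e-10)
  }
})

test_that("TMLE recovers a known effect on unconfounded synthetic data", {
  cfg <- sim_config(n = 4000, seed = 17,
                    propensity = list(intercept = -0.4, coef = numeric(0)),
                    outcome = list(intercept = -2.2, treatment = 1.4,
                                   coef = c(bmi = 0.06, magnesium = 0.5)))
  gen <- generate_cohort(cfg, truth_mc_size = 4e5)
  fit <- tmle_estimate(gen$cohort, fast_config(seed = 18))
  expect_lt(abs(fit$estimate - gen$truth$rd), 3 * fit$se)
  expect_lt(abs(mean(fit$ic)), 1e-8)
  # randomized design: mean truncated PS near the assignment probability
  expect_lt(abs(mean(fit$nuisances$g_trunc) - plogis(-0.4)), 0.03)
})

test_that("relabeling treatment negates the RD and inverts RR/OR", {
  ch <- make_discrete_cohort(n = 280, seed = 23)
  nf <- saturated_nuisances(ch)
  fit <- tmle_estimate(ch, run_config(), nuisances = nf)
  ch_sw <- cohort(y = ch$y, a = 1 - ch$a, w = ch$w)
  nf_sw <- tlroadmap:::nuisance_fits(nf$qbar, q1 = nf$q0, q0 = nf$q1,
                                     g = 1 - nf$g, bound = nf$bound,
                                     truncate = FALSE)
  fit_sw <- tmle_estimate(ch_sw, run_config(), nuisances = nf_sw)
  expect_equal(fit_sw$estimate, -fit$estimate, tolerance = 1e-12)
  rr <- effect_on_scale(fit$psi1, fit$psi0, fit$ic1, fit$ic0, "RR")
  rr_sw <- effect_on_scale(fit_sw$psi1, fit_sw$psi0, fit_sw$ic1, fit_sw$ic0,
                           "RR")
  expect_equal(rr_sw$estimate, 1 / rr$estimate, tolerance = 1e-10)
})

test_that("truncation is a no-op when all propensities are interior", {
  ch <- make_discrete_cohort(n = 300, seed = 29)
  nf_t <- saturated_nuisances(ch, bound = 0.02, truncate = TRUE)
  nf_u <- saturated_nuisances(ch, bound = 0.02, truncate = FALSE)
  expect_true(all(nf_u$g > 0.02 & nf_u$g < 0.98))
  fit_t <- tmle_estimate(ch, run_config(), nuisances = nf_t)
  fit_u <- tmle_estimate(ch, run_config(), nuisances = nf_u)
  expect_identical(fit_t$estimate, fit_u$estimate)
  expect_identical(fit_t$se, fit_u$se)
})

test_that("effect scales transform arm means correctly", {
  ic <- rnorm(100, sd = 0.01)
  null_eff <- effect_on_scale(0.3, 0.3, ic, ic, "RR")
  expect_equal(null_eff$estimate, 1)
  expect_equal(effect_on_scale(0.3, 0.3, ic, ic, "OR")$estimate, 1)
  expect_equal(effect_on_scale(0.5, 0.25, ic, ic, "RR")$estimate, 2)
  expect_equal(effect_on_scale(0.5, 0.25, ic, ic, "OR")$estimate, 3)
  expect_error(effect_on_scale(0.5, 0, ic, ic, "RR"), "inside")
})

test_that("delta-method log-RR standard error agrees with the bootstrap", {
  # single-stratum cohort: the targeted arm means are the crude arm means,
  # so a nonparametric bootstrap of log(ybar1/ybar0) is an independent oracle
  ch <- with_test_seed(31, {
    a <- rbinom(400, 1, 0.5)
    y <- rbinom(400, 1, 0.2 + 0.25 * a)
    cohort(y = y, a = a, w = cbind(w = rep(1, 400)))
  })
  fit <- tmle_estimate(ch, run_config(scale = "RR"),
                       nuisances = saturated_nuisances(ch))
  boot <- with_test_seed(32, replicate(2000, {
    i <- sample.int(ch$n, replace = TRUE)
    log(mean(ch$y[i][ch$a[i] == 1]) / mean(ch$y[i][ch$a[i] == 0]))
  }))
  expect_equal(fit$se, sd(boot), tolerance = 0.15)
})

test_that("globally empty arms abort estimation", {
  ch <- cohort(y = c(0, 1, 0), a = c(1, 1, 1), w = cbind(w = 1:3))
  expect_error(fit_nuisances(ch, run_config()), "positivity")
})
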