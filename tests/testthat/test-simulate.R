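test_that("generation is deterministic down to the emitted CSV bytes", {
  cfg <- sim_config(n = 80, seed = 42)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(generate_cohort(cfg, truth_mc_size = 1e4)$cohort, f1)
  write_cohort(generate_cohort(cfg, truth_mc_size = 1e4)$cohort, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("truth oracle matches the closed form when the outcome ignores W", {
  # logit risk = -2 + 1*A  =>  true RD = expit(-1) - expit(-2)
  cfg <- sim_config(n = 100, seed = 3,
                    outcome = list(intercept = -2, treatment = 1,
                                   coef = numeric(0)))
  tr <- true_effect_oracle(cfg, mc_size = 2e5)
  closed <- plogis(-1) - plogis(-2)
  expect_equal(closed, 0.1497385, tolerance = 1e-6)
  expect_lt(abs(tr$rd - closed), 3 * tr$mc_se)
  expect_equal(tr$delta, 0)  # no hidden structure configured
})

test_that("null treatment effect yields a null true RD", {
  cfg <- sim_config(n = 100, seed = 5,
                    outcome = list(intercept = -2, treatment = 0,
                                   coef = c(bmi = 0.07, age = 0.03)))
  tr <- true_effect_oracle(cfg, mc_size = 1e5)
  expect_lt(abs(tr$rd), 3 * tr$mc_se)
})

test_that("arm-swapped outcome coefficients negate the true RD", {
  # swapping arms: intercept' = intercept + t, treatment' = -t makes the
  # forced-A=1 world of one configuration the forced-A=0 world of the other
  tr_p <- true_effect_oracle(
    sim_config(outcome = list(intercept = -1.5, treatment = 0.8,
                              coef = c(magnesium = 0.4)), seed = 11),
    mc_size = 2e5)
  tr_m <- true_effect_oracle(
    sim_config(outcome = list(intercept = -1.5 + 0.8, treatment = -0.8,
                              coef = c(magnesium = 0.4)), seed = 11),
    mc_size = 2e5)
  expect_lt(abs(tr_p$rd + tr_m$rd), 3 * sqrt(tr_p$mc_se^2 + tr_m$mc_se^2))
})

test_that("doubling the Monte-Carlo size agrees within combined error", {
  cfg <- sim_config(seed = 9)
  t1 <- true_effect_oracle(cfg, mc_size = 5e4, seed = 101)
  t2 <- true_effect_oracle(cfg, mc_size = 1e5, seed = 202)
  expect_lt(abs(t1$rd - t2$rd), 4 * sqrt(t1$mc_se^2 + t2$mc_se^2))
})

test_that("contra-indicated stratum is exactly floor(f*n) structurally untreated", {
  cfg <- sim_config(n = 103, seed = 21, contraindication_fraction = 0.2)
  gen <- generate_cohort(cfg, truth_mc_size = 1e4)
  cc <- gen$hidden$contraindicated
  expect_equal(sum(cc), floor(0.2 * 103))
  expect_true(all(gen$cohort$a[cc == 1] == 0))
})

test_that("an unmeasured confounder biases the crude RD in the expected direction", {
  cfg <- sim_config(n = 4e4, seed = 31, confounder_strength = 1.5)
  gen <- generate_cohort(cfg, truth_mc_size = 2e5)
  ch <- gen$cohort
  crude <- mean(ch$y[ch$a == 1]) - mean(ch$y[ch$a == 0])
  crude_se <- sqrt(var(ch$y[ch$a == 1]) / sum(ch$a) +
                     var(ch$y[ch$a == 0]) / sum(1 - ch$a))
  # confounding is real: crude differs from truth, upward for a +/+ confounder
  expect_gt(crude - gen$truth$rd, 3 * sqrt(crude_se^2 + gen$truth$mc_se^2))
  expect_gt(gen$truth$delta, 0)
})

test_that("injected causal gap equals the W-adjusted-minus-causal discrepancy", {
  # one binary covariate keeps W discrete, so the W-adjusted estimand can be
  # estimated nonparametrically (stratified g-computation) on a huge cohort
  # and compared against the recorded delta
  cfg <- sim_config(
    n = 1.2e5, seed = 41,
    covariates = list(list(name = "w1", family = "bernoulli",
                           params = list(p = 0.4))),
    propensity = list(intercept = -0.6, coef = c(w1 = 0.7)),
    outcome = list(intercept = -1.6, treatment = 0.9, coef = c(w1 = 0.5)),
    confounder_strength = 1.4)
  gen <- generate_cohort(cfg, truth_mc_size = 4e5)
  psi_stat_hat <- gcomp_oracle(gen$cohort)
  expect_lt(abs(psi_stat_hat - gen$truth$psi_stat), 0.015)
  expect_equal(gen$truth$rd, gen$truth$psi1 - gen$truth$psi0,
               tolerance = 1e-12)
  expect_gt(gen$truth$delta, 0)
})

test_that("dose cohorts hit the configured crude event-rate pattern", {
  targets <- c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.25)
  cfg <- sim_config(n = 2e4, seed = 51,
                    dose = list(group_event_rates = targets))
  ch <- generate_dose_cohort(cfg)
  tab <- crude_dose_proportions(ch$dose, ch$y)
  expect_true(all(tab$n > 0))
  se <- sqrt(targets * (1 - targets) / tab$n)
  expect_true(all(abs(tab$proportion - targets) < 3 * se))
  expect_true(attr(tab, "non_monotonic"))  # rises to group 5, then falls
  # untreated dose exactly zero, treated strictly positive
  expect_true(all(ch$dose[ch$a == 0] == 0))
  expect_true(all(ch$dose[ch$a == 1] > 0))
})

test_that("dose model edge cases behave", {
  expect_error(sim_config(dose = list(group_event_rates = c(0.1, 0.2, 0.3,
                                                            1.2, 0.4, 0.5,
                                                            0.6))),
               "\\(0, 1\\)")
  # flat targets: crude curve flat up to binomial noise
  flat <- sim_config(n = 5000, seed = 61,
                     dose = list(group_event_rates = rep(0.2, 7)))
  chf <- generate_dose_cohort(flat)
  tab <- crude_dose_proportions(chf$dose, chf$y)
  expect_true(all(abs(tab$proportion - 0.2) <
                    3 * sqrt(0.2 * 0.8 / tab$n)))
  # n below the group count: empty groups are flagged, not an error
  tiny <- sim_config(n = 4, seed = 71,
                     dose = list(group_event_rates = rep(0.2, 7)))
  ch <- generate_dose_cohort(tiny)
  expect_true(length(attr(ch, "empty_groups")) > 0)
})
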