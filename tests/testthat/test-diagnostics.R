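test_that("the bundled age table carries the expected positivity violations", {
  tab <- ritodrine_age_table()
  expect_equal(sum(tab$control) + sum(tab$treated), 225)
  expect_equal(tab$category[tab$empty_treated], c("16-20", "46-50"))
  expect_false(any(tab$empty_control))
})

test_that("collapsing age categories removes the violation and preserves totals", {
  tab <- ritodrine_age_table()
  col <- collapse_categories(tab, ritodrine_age_collapse())
  expect_equal(col$category, c("16-30", "31-35", "36-50"))
  expect_equal(col$control, c(48, 50, 45))
  expect_equal(col$treated, c(33, 29, 20))
  expect_false(any(col$empty_treated | col$empty_control))
  expect_equal(sum(col$control), sum(tab$control))
  expect_equal(sum(col$treated), sum(tab$treated))

  # identity mapping leaves the table unchanged
  id_map <- setNames(tab$category, tab$category)
  expect_equal(collapse_categories(tab, id_map)$control, tab$control)

  # merging non-adjacent categories is not a coarsening
  bad <- setNames(tab$category, tab$category)
  bad["16-20"] <- "ends"
  bad["46-50"] <- "ends"
  expect_error(collapse_categories(tab, bad), "contiguous")
  expect_error(collapse_categories(tab, bad["16-20"]), "cover")
})

test_that("collapsing conserves counts for arbitrary contiguous mappings", {
  for (s in 1:5) {
    tab <- with_test_seed(s, positivity_table(
      sample(letters[1:6], 120, replace = TRUE),
      rbinom(120, 1, 0.4)))
    k <- nrow(tab)
    cutpts <- with_test_seed(s + 100,
                             sort(sample(seq_len(k - 1),
                                         sample(k - 1, 1))))
    new <- cumsum(c(1, seq_len(k - 1) %in% cutpts))
    map <- setNames(paste0("grp", new), tab$category)
    col <- collapse_categories(tab, map)
    expect_equal(sum(col$control), sum(tab$control))
    expect_equal(sum(col$treated), sum(tab$treated))
    expect_equal(sum(col$control) + sum(col$treated), 120)
  }
})

test_that("positivity table flags exactly the empty arms", {
  tab <- positivity_table(rep("only", 5), c(1, 1, 0, 1, 0))
  expect_false(any(tab$empty_treated | tab$empty_control))
  tab_all1 <- positivity_table(c("a", "a", "b"), c(1, 1, 1))
  expect_true(all(tab_all1$empty_control))
  expect_false(any(tab_all1$empty_treated))
})

test_that("positivity flags are at least as strict as the oracle's errors", {
  ch <- cohort(y = c(0, 1, 0, 1, 0), a = c(0, 0, 1, 0, 1),
               w = cbind(grp = c(0, 0, 1, 1, 1)))
  tab <- positivity_table(ch$w[, "grp"], ch$a)
  expect_true(tab$empty_treated[tab$category == "0"])
  expect_error(gcomp_oracle(ch), "positivity")
})

test_that("the propensity C-statistic is a tie-aware concordance", {
  expect_equal(ps_cstat(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(ps_cstat(rep(0.4, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_equal(ps_cstat(c(0.2, 0.4, 0.6, 0.9), c(0, 1, 0, 1)), 0.75)
  expect_error(ps_cstat(c(0.2, 0.3), c(1, 1)), "both arms")
})

test_that("the C-statistic is invariant to strictly increasing transforms", {
  g <- with_test_seed(3, runif(200))
  a <- with_test_seed(4, rbinom(200, 1, g))
  base <- ps_cstat(g, a)
  expect_equal(ps_cstat(qlogis(g), a), base)
  expect_equal(ps_cstat(g^3, a), base)
  expect_equal(ps_cstat(rank(g), a), base)
})

test_that("overlap summaries behave on identical and disjoint arms", {
  g <- c(0.2, 0.2, 0.6, 0.6)
  ident <- ps_overlap_summary(g, c(0, 1, 0, 1), bins = 5)
  expect_equal(ident$prop_treated, ident$prop_control)
  expect_equal(ident$overlap_mass, 1)

  disj <- ps_overlap_summary(c(0.1, 0.15, 0.8, 0.9), c(0, 0, 1, 1),
                             bins = 10)
  expect_equal(disj$overlap_mass, 0)

  ov <- ps_overlap_summary(c(0.3, 0.4, 0.5), c(0, 1, 1), bound = 0.06)
  expect_true(ov$truncation_noop)
  ov2 <- ps_overlap_summary(c(0.03, 0.4, 0.5), c(0, 1, 1), bound = 0.06)
  expect_false(ov2$truncation_noop)
  expect_equal(ov2$n_outside_bound, 1)
})

test_that("dose groups are a half-open partition of the dose axis", {
  expect_equal(dose_group(c(0, 5, 15, 55)), c(0, 1, 2, 6))
  expect_equal(dose_group(10), 1L)    # boundary belongs to the lower group
  expect_equal(dose_group(10.5), 2L)
  expect_error(dose_group(-1), "negative")

  d <- with_test_seed(5, c(0, round(runif(400, 0, 70), 2)))
  g <- dose_group(d)
  expect_true(all(g %in% 0:6))
  expect_equal(g == 0, d == 0)

  tab <- crude_dose_proportions(c(0, 5, 15, 55), c(0, 1, 0, 1))
  expect_equal(tab$proportion[tab$group %in% c(0, 1, 2, 6)], c(0, 1, 0, 1))
  expect_equal(tab$n[tab$group %in% c(3, 4, 5)], rep(0L, 3))
  expect_true(all(is.na(tab$proportion[tab$n == 0])))
})

test_that("non-monotonic crude patterns are flagged", {
  tab <- crude_dose_proportions(c(0, 5, 15, 25), c(0, 1, 0, 0))
  # proportions 0, 1, 0, 0 over groups 0..3 -> rises then falls
  expect_true(attr(tab, "non_monotonic"))
  inc <- crude_dose_proportions(c(0, 5, 15), c(0, 1, 1))
  expect_false(attr(inc, "non_monotonic"))
})

test_that("the baseline logistic dose model recovers simulated odds ratios", {
  # null dose effect
  ch0 <- with_test_seed(7, {
    n <- 4000
    a <- rbinom(n, 1, 0.5)
    dose <- ifelse(a == 1, runif(n, 1, 60), 0)
    w <- cbind(x = rnorm(n))
    y <- rbinom(n, 1, plogis(-1.5 + 0.3 * w[, 1]))
    cohort(y = y, a = a, w = w, dose = dose)
  })
  res0 <- baseline_logistic_or(ch0)
  expect_true(res0$ci[1] < 1 && 1 < res0$ci[2])

  # log-OR 0.02 per dose unit
  ch1 <- with_test_seed(8, {
    n <- 10000
    a <- rbinom(n, 1, 0.5)
    dose <- ifelse(a == 1, runif(n, 1, 60), 0)
    w <- cbind(x = rnorm(n))
    y <- rbinom(n, 1, plogis(-2 + 0.02 * dose + 0.3 * w[, 1]))
    cohort(y = y, a = a, w = w, dose = dose)
  })
  res1 <- baseline_logistic_or(ch1)
  expect_lt(abs(res1$log_or - 0.02), 3 * res1$se_log_or)
  expect_error(baseline_logistic_or(make_discrete_cohort(100, 1)),
               "no dose")
})
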