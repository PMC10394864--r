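---
title: "Methods: a Targeted Learning roadmap for point-treatment effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Targeted Learning roadmap for point-treatment effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlroadmap)
```

## The problem and the estimand

The package answers a deliberately modest causal question: for a cohort of
i.i.d. observations `O = (Y, A, W)` with binary outcome `Y`, binary
treatment `A` (any exposure vs. none), and baseline covariates `W`, what is
the marginal risk difference

$$\psi = E\big[E(Y \mid A=1, W) - E(Y \mid A=0, W)\big]?$$

The motivating setting is a retrospective cohort of 225 twin pregnancies in
which ritodrine tocolysis is assessed against maternal pulmonary edema. A
causal dose–response curve is *not* targeted: when the relative timing of
dose accumulation, time-varying covariates, and the outcome is not recorded
— and when clinicians may lower the dose *because* the outcome occurred —
no statistical functional of such data corresponds to the counterfactual
dose curve. The package therefore treats dose only descriptively
(`crude_dose_proportions()`, the seven-group display with its
non-monotonicity flag) and estimates the any-vs-none contrast, which needs
only baseline confounding control.

Three assumptions give $\psi$ its causal reading: consistency (observed
outcome equals the counterfactual under the received treatment — satisfied
by construction for the any-vs-none coding), positivity (every covariate
stratum has a positive probability of each arm), and no unmeasured
confounding. The package's stance is that the first is a definition, the
second is *checkable* (and checked), and the third is *not checkable* —
hence the sensitivity module rather than a blanket claim.

## Estimation

### Super learner

Both nuisance functions — the outcome regression $\bar Q(A,W)$ and the
propensity score $g(W)$ — are estimated by a V-fold cross-validated convex
ensemble. Out-of-fold predictions from each library member are combined
with simplex weights minimizing the cross-validated negative Bernoulli
log-likelihood; the optimization uses a softmax parametrization polished
against every vertex, so a single dominant learner is recovered exactly and
the ensemble's CV risk can never exceed the best single learner's. Folds
are stratified on the binary response: with ~30 events in 225 subjects and
V = 20 (the default), unstratified folds would regularly contain no events
at all, making the Bernoulli loss degenerate on those folds.

The built-in library is: unpenalized logistic regression; lasso-penalized
logistic regression (`glmnet`, penalty chosen by an inner 5-fold CV run on
the training folds only, with deterministic fold ids — no leakage, no
hidden randomness); a spline-additive logistic GAM (`mgcv`, basis dimension
4 per continuous covariate) standing in for the generalized additive model
role; and a probability random forest (`ranger`, 200 trees, minimum node
size 10) standing in for the flexible tree-ensemble (BART-type) role.
Exact replication of a particular BART implementation is a non-goal; the
library role it fills — a flexible learner that can capture interactions
and non-linearities — is what matters for the ensemble. A learner that
errors on a fold contributes the training-fold event rate for that fold and
the failure is logged; a library member's fragility must not crash an
analysis.

### TMLE

The initial $\bar Q$ is updated along the one-dimensional least-favorable
submodel
$\text{logit}\,\bar Q^*(A,W) = \text{logit}\,\bar Q(A,W) + \varepsilon H(A,W)$
with the signed clever covariate $H(A,W) = A/g(W) - (1-A)/(1-g(W))$. One
$\varepsilon$ with the signed covariate (rather than two arm-specific
coefficients) matches the convention of the standard point-treatment TMLE
software and solves the efficient-influence-function equation for the ATE.
$\varepsilon$ is fit by Newton iterations on the offset-logistic score
(tolerance $10^{-12}$, at most 100 steps; the one-parameter log-likelihood
is concave and $H$ is bounded by the truncation, so convergence is
essentially guaranteed and is verified to $10^{-9}$ after the loop).

The propensity is truncated two-sided to $[b, 1-b]$ with
$b = 5/(\sqrt{n}\,\ln n)$ by default — 0.0615 at $n = 225$. The exact
formula value is used internally; reports also carry it rounded to two
decimals (0.06) for comparability with conventional reporting. When no
prediction falls outside the bounds, truncation is verifiably a no-op and
the overlap summary says so.

Inference is influence-curve based:
$IC_i = H(A_i,W_i)(Y_i - \bar Q^*(A_i,W_i)) + \bar Q^*(1,W_i) - \bar
Q^*(0,W_i) - \hat\psi$, $\hat\sigma = sd(IC)/\sqrt n$, Wald intervals with
exact normal quantiles (1.96 is treated as the rounded 97.5% quantile; a
`z` argument forces 1.96 where printed-arithmetic compatibility is wanted).
Risk ratios and odds ratios are delta-method transforms of the targeted arm
means with intervals built on the log scale — an extension beyond the
risk-difference focus of the motivating analysis, following standard
practice. No cross-fitted (CV-)TMLE is implemented; the motivating analysis
used plain TMLE, and cross-fitting is noted as a possible extension.

### Oracles used in testing

Two independent routes check the estimator rather than re-deriving it:
a fully stratified g-computation plug-in (`gcomp_oracle()`) for discrete
covariates — TMLE with saturated nuisance fits must agree with it to
$10^{-6}$, since both are then the nonparametric MLE — and a Monte-Carlo
counterfactual oracle (`true_effect_oracle()`) that simulates outcomes
under forced treatment and forced control. Parameter recovery is tested
over 200 simulated confounded cohorts of n = 1000 (bias below 0.01,
coverage within [0.91, 0.985]); that test uses the logistic-only library
with V = 10, which is well-specified for the generator and keeps the suite
fast.

## Identifiability diagnostics

`positivity_table()` cross-tabulates each covariate (continuous ones binned
at quartiles) against the arm and flags empty cells; `run_roadmap()` can be
set to abort on flags (strict mode) or to warn and proceed under truncation
(permissive mode, the default). Both behaviors are legitimate: an empty
cell in a clinically meaningful stratum can sometimes be cured by
`collapse_categories()` — only order-respecting merges are allowed, and
counts are conserved — and sometimes means the question must change. The
packaged age table for the motivating cohort (`ritodrine_age_table()`)
shows both: the original 5-year groupings have two age groups with no
treated women, and the coarsened 16–30 / 31–35 / 36–50 grouping removes the
violation.

The C-statistic of the propensity fit uses the Mann–Whitney tie convention
(ties count one half); it is invariant to monotone transforms of `g`. Note
that it is computed on in-sample fitted values: a flexible learner with
non-trivial ensemble weight can inflate it well above the discrimination of
the true assignment mechanism (the worked example in the README shows 0.93
where the generating truth is about 0.70). It is reported as an overlap
description, not a model-quality score.

## Sensitivity: causal gap and G-value

Let $\delta = \psi^{stat} - \psi^{causal}$ be the causal gap. Under the
package's shift convention the bias-corrected estimate is
$\hat\psi - \delta$, so the scan subtracts each hypothesized $\delta$ from
the estimate and both CI bounds, reports gaps in SE units, and computes in
closed form the gap that nullifies the finding (nearer CI bound reaches
the null; its magnitude is the G-value) and the gap that reverses it
(farther bound crosses the null). For ratio scales the machinery operates
on the log scale with null $\log 1 = 0$.

Two printed-rounding facts are deliberately not chased: with estimate 0.21
and SE 0.062 the reverse threshold is $0.21 + 1.96 \times 0.062 = 0.3315$
(sometimes quoted as "> 0.325", consistent with an unrounded SE), and the
G-value in SE units is $0.0885/0.062 = 1.43$ (sometimes quoted as 1.5).
The package reports unrounded closed-form values and leaves rounding to the
caller.

## The synthetic-cohort generator

The generator (`sim_config()`, `generate_cohort()`) emulates the
*structure* the analysis assumes, not any real data set's empirical
marginals: ten baseline covariates (discretized-normal age; correlated
normal height and weight; BMI derived from them; an obesity indicator; five
Bernoulli indicators), a logistic treatment assignment, and a logistic
outcome model with a treatment main effect. The default coefficients were
fixed once so that a default cohort looks like the motivating study's
skeleton: n = 225, ~36% treated, event rate ~0.14, true risk difference
~0.21, propensity discrimination (C-statistic of the true mechanism) ~0.70.
No distributional calibration to the real cohort is attempted, and passing
tests on generated data therefore demonstrate estimator correctness under a
well-behaved, correctly structured world — not robustness to the messiness
(measurement error, missingness, informative dosing) of real registry data.

Two controllable violations make the sensitivity machinery testable:

- an unmeasured Bernoulli confounder `U` entering both linear predictors —
  the simplest mechanism with a sign-interpretable gap. The recorded
  `delta` is computed by marginalizing the hidden structure analytically
  within the Monte-Carlo oracle ($E(Y|A,W)$ is a mixture over `U` tilted by
  conditioning on `A`), and is verified in tests against a stratified
  nonparametric estimate on a large generated cohort;
- a structurally untreated (contra-indicated) stratum of exactly
  `floor(f*n)` subjects, emulating prescribing contra-indications that are
  absent from the covariate record.

Dose, when generated, is positive for treated subjects only (any-vs-none
coding is exact by construction) and is spread over the six positive dose
groups with per-group event-rate targets, so the crude seven-group display
can be given any shape — including the rising-then-falling pattern that
motivates distrusting a linear dose term.

Randomness is organized as one root seed with per-stage child streams, so
adding a covariate cannot perturb the treatment draws; identical
configurations produce byte-identical CSV output.

## Numerical choices and edge cases

- Probabilities are clipped to $[10^{-6}, 1-10^{-6}]$ before logits and
  log-likelihoods.
- Simplex weight optimization: softmax-parametrized BFGS with Nelder–Mead
  polish (`optimize()` in the two-learner case), then a vertex sweep; the
  returned weights never lose to a vertex by more than $10^{-8}$.
- Cohorts with missing values are rejected, not imputed; imputation would
  silently change the estimand.
- A globally empty arm is an error (no contrast exists); an empty stratum
  cell is a flag (strict mode: abort) because collapsing may cure it.
- Degenerate simulation configs (near-certain all-treated draws) produce a
  recorded warning, not a failure.
- Dose bins are half-open on the left, $(0,10], (10,20], \ldots$: boundary
  dose 10 belongs to the first positive group, and group 0 contains exactly
  the untreated. The convention is configurable via the cut points.

## Problem sizes in the test suite

The suite favors small, structured problems where independent oracles are
exact: discrete-covariate cohorts of 250–400 subjects for the NPMLE
equivalence checks, 200 replicate cohorts of n = 1000 for bias/coverage,
single large cohorts (up to 1.2e5) where a Monte-Carlo or stratified
estimate must pin down a generator property. These sizes were chosen so
each property is tested at a precision that would expose a real defect.

## Known limitations

- No longitudinal estimands, no censoring or missing-outcome machinery.
- No cross-fitted TMLE; with very aggressive learners in small samples the
  non-cross-fitted estimator can inherit some overfitting bias.
- The forest and GAM learners are stand-ins for the BART and GAM choices of
  the motivating analysis, not replicas; ensemble weights will differ.
- The G-value and gap scan treat $\hat\sigma$ as fixed under the gap — the
  standard first-order convention for this analysis, ignoring any effect of
  the violation on the variance.
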