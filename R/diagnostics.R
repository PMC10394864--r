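#' Positivity table: arm counts per category
#'
#' Cross-tabulates a categorical baseline variable against the treatment
#' indicator and flags categories with an empty arm.  An empty treated (or
#' control) cell means the arm-specific outcome mean is not estimable in
#' that stratum: the marginal contrast is not identified without collapsing
#' categories or changing the question.
#'
#' @param values categorical vector (factor, character, or discrete
#'   numeric); factor level order is respected.
#' @param a binary treatment vector of the same length.
#' @return A `tl_stratum_table` data frame with columns `category`,
#'   `control`, `treated`, `empty_treated`, `empty_control`.
#' @export
positivity_table <- function(values, a) {
  stopifnot(length(values) == length(a))
  f <- if (is.factor(values)) values else factor(values)
  tab <- table(f, factor(a, levels = c(0, 1)))
  out <- data.frame(category = rownames(tab),
                    control = as.integer(tab[, "0"]),
                    treated = as.integer(tab[, "1"]),
                    stringsAsFactors = FALSE)
  out$empty_treated <- out$treated == 0L
  out$empty_control <- out$control == 0L
  class(out) <- c("tl_stratum_table", "data.frame")
  out
}

#' Collapse adjacent categories of a positivity table
#'
#' Sums arm counts within new labels.  Only order-respecting collapses are
#' allowed: the old categories mapped to one new label must be contiguous in
#' the original ordering (merging, say, the youngest and oldest age groups
#' while skipping the middle would not be a coarsening).  Arm totals and the
#' grand total are preserved.
#'
#' @param table a `tl_stratum_table`.
#' @param mapping named character vector: `old label -> new label`, covering
#'   every category.
#' @return A collapsed `tl_stratum_table` (flags recomputed).
#' @examples
#' tab <- positivity_table(rep(c("16-20", "21-25", "26-30"), c(2, 16, 63)),
#'                         rep(c(0, 0, 1, 0, 1), c(2, 9, 7, 37, 26)))
#' collapse_categories(tab, c("16-20" = "16-30", "21-25" = "16-30",
#'                            "26-30" = "16-30"))
#' @export
collapse_categories <- function(table, mapping) {
  stopifnot(inherits(table, "tl_stratum_table"))
  absent <- setdiff(table$category, names(mapping))
  if (length(absent)) {
    stop("mapping does not cover categories: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  new_lab <- unname(mapping[table$category])
  # contiguity: each new label must occupy one unbroken run of rows
  runs <- rle(new_lab)$values
  if (anyDuplicated(runs)) {
    stop("non-contiguous merge: categories mapped to one label must be ",
         "adjacent in the original ordering", call. = FALSE)
  }
  out <- data.frame(
    category = runs,
    control = as.integer(tapply(table$control, factor(new_lab, levels = runs),
                                sum)),
    treated = as.integer(tapply(table$treated, factor(new_lab, levels = runs),
                                sum)),
    stringsAsFactors = FALSE)
  out$empty_treated <- out$treated == 0L
  out$empty_control <- out$control == 0L
  rownames(out) <- NULL
  class(out) <- c("tl_stratum_table", "data.frame")
  out
}

#' Concordance statistic (C-statistic) of the propensity score
#'
#' Probability that a randomly chosen treated subject has a higher predicted
#' propensity than a randomly chosen control subject, with ties counted one
#' half (the Mann-Whitney convention); equivalently the area under the ROC
#' curve of `g` against `a`.
#'
#' @param g propensity predictions.
#' @param a binary treatment vector.
#' @return The concordance probability in \[0, 1\].
#' @examples
#' ps_cstat(c(0.2, 0.4, 0.6, 0.9), c(0, 1, 0, 1))  # 0.75
#' @export
ps_cstat <- function(g, a) {
  stopifnot(length(g) == length(a), is_binary01(a))
  n1 <- sum(a)
  n0 <- sum(1 - a)
  if (n1 == 0 || n0 == 0) {
    stop("C-statistic requires both arms non-empty", call. = FALSE)
  }
  r <- rank(g)  # average ranks give the half-credit tie convention
  (sum(r[a == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Propensity overlap summary
#'
#' Per-arm histogram proportions over a shared bin grid on \[0, 1\], per-arm
#' ranges, a shared-bin overlap mass statistic
#' (\eqn{\sum_b \min(p_{1b}, p_{0b})}), and — when a truncation bound is
#' supplied — the count of predictions at or outside `[bound, 1 - bound]`
#' and a flag saying whether truncation is a no-op.
#'
#' @param g propensity predictions.
#' @param a binary treatment vector.
#' @param bins number of equal-width bins (>= 2).
#' @param bound optional truncation bound.
#' @return A list: `breaks`, `prop_treated`, `prop_control`, `overlap_mass`,
#'   `range_treated`, `range_control`, and when `bound` is given
#'   `n_outside_bound`, `truncation_noop`.
#' @export
ps_overlap_summary <- function(g, a, bins = 10L, bound = NULL) {
  stopifnot(bins >= 2L, length(g) == length(a))
  breaks <- seq(0, 1, length.out = bins + 1L)
  cut_idx <- findInterval(g, breaks, rightmost.closed = TRUE,
                          all.inside = TRUE)
  p1 <- tabulate(cut_idx[a == 1], bins) / max(sum(a == 1), 1L)
  p0 <- tabulate(cut_idx[a == 0], bins) / max(sum(a == 0), 1L)
  out <- list(breaks = breaks, prop_treated = p1, prop_control = p0,
              overlap_mass = sum(pmin(p1, p0)),
              range_treated = if (any(a == 1)) range(g[a == 1]) else c(NA, NA),
              range_control = if (any(a == 0)) range(g[a == 0]) else c(NA, NA))
  if (!is.null(bound)) {
    out$n_outside_bound <- sum(g <= bound | g >= 1 - bound)
    out$truncation_noop <- out$n_outside_bound == 0L
  }
  out
}

#' Seven total-dose groups
#'
#' Partition of the non-negative dose axis (72 mg/24 h units) into the
#' no-treatment group 0 (dose exactly 0) and six half-open intervals
#' `(0, 10], (10, 20], ..., (50, Inf)` labelled 1..6.  The integer group
#' labels "> 0-10, 11-20, ..." are read as half-open bins so that every
#' continuous dose falls in exactly one group.
#'
#' @param dose non-negative dose vector.
#' @param cuts upper cut points of the finite groups (default
#'   `c(0, 10, 20, 30, 40, 50)`).
#' @return Integer group ids in `0:length(cuts)`.
#' @export
dose_group <- function(dose, cuts = c(0, 10, 20, 30, 40, 50)) {
  if (any(dose < 0)) stop("negative dose", call. = FALSE)
  g <- integer(length(dose))
  pos <- dose > 0
  # findInterval on (0,10],(10,20],... : left-open achieved by strict bounds
  g[pos] <- vapply(dose[pos], function(d) {
    sum(d > cuts)
  }, 0L)
  g
}

#' Crude event proportions by dose group
#'
#' Assigns every subject to one of the seven dose groups and reports group
#' size, event count, and crude proportion, plus a non-monotonicity flag on
#' the observed proportions (over non-empty groups).  This backs the crude
#' dose-response display; it carries no causal interpretation.
#'
#' @param dose non-negative dose vector.
#' @param y binary outcome vector.
#' @param cuts upper cut points of the finite dose groups.
#' @return A data frame with `group`, `label`, `n`, `events`, `proportion`
#'   (NA for empty groups) and attribute `"non_monotonic"`.
#' @export
crude_dose_proportions <- function(dose, y, cuts = c(0, 10, 20, 30, 40, 50)) {
  stopifnot(length(dose) == length(y))
  grp <- dose_group(dose, cuts)
  k <- length(cuts)
  labels <- c("0", paste0("(", cuts, ",",
                          c(cuts[-1], Inf), "]")[seq_len(k)])
  labels[k + 1L] <- paste0("(", cuts[k], ",Inf)")
  out <- data.frame(group = 0:k, label = labels)
  out$n <- vapply(0:k, function(gg) sum(grp == gg), 0L)
  out$events <- vapply(0:k, function(gg) sum(y[grp == gg]), 0)
  out$proportion <- ifelse(out$n > 0, out$events / out$n, NA_real_)
  p <- out$proportion[!is.na(out$proportion)]
  attr(out, "non_monotonic") <-
    length(p) > 2 && !all(diff(p) >= 0) && !all(diff(p) <= 0)
  out
}

#' Main-terms logistic dose model (baseline comparison)
#'
#' The conventional analysis this package's roadmap is contrasted with: a
#' maximum-likelihood logistic regression of the outcome on the continuous
#' total dose plus main-term covariates, reporting the exponentiated dose
#' coefficient (odds ratio per dose unit) with a Wald interval.  Entering
#' dose as a continuous main term imposes a monotonic dose-response a
#' priori; the estimate is provided only for comparison, not as a causal
#' quantity.
#'
#' @param cohort a [cohort()] with a dose column.
#' @param covariate_cols covariate columns to adjust for (default: all).
#' @param level confidence level.
#' @return List with `or` (per dose unit), `ci`, `log_or`, `se_log_or`,
#'   and the fitted `glm`.
#' @export
baseline_logistic_or <- function(cohort, covariate_cols = NULL,
                                 level = 0.95) {
  stopifnot(inherits(cohort, "tl_cohort"))
  if (is.null(cohort$dose)) {
    stop("cohort has no dose column", call. = FALSE)
  }
  covs <- covariate_cols %||% colnames(cohort$w)
  df <- data.frame(y = cohort$y, dose = cohort$dose,
                   cohort$w[, covs, drop = FALSE], check.names = TRUE)
  fit <- stats::glm(y ~ ., data = df, family = stats::binomial())
  sm <- summary(fit)$coefficients
  if (!fit$converged || !"dose" %in% rownames(sm) ||
      sm["dose", "Std. Error"] > 50) {
    stop("logistic dose model unstable (separation or non-convergence); ",
         "dose coefficient SE = ",
         if ("dose" %in% rownames(sm)) signif(sm["dose", "Std. Error"], 3)
         else "unavailable", call. = FALSE)
  }
  b <- sm["dose", "Estimate"]
  se <- sm["dose", "Std. Error"]
  list(or = exp(b), ci = exp(wald_ci(b, se, level)),
       log_or = b, se_log_or = se, fit = fit)
}
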