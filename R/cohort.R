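#' Construct and validate a point-treatment cohort
#'
#' A cohort holds the observed data structure `O = (Y, A, W)` for a binary
#' point-treatment question: a binary outcome `y`, a binary treatment
#' indicator `a`, an optional non-negative total-dose variable (in units of
#' 72 mg/24 h for the motivating ritodrine cohort), and a numeric matrix of
#' baseline covariates `w`.  Any-vs-none treatment coding is enforced: when a
#' dose is present, `a = 1` exactly when `dose > 0`.
#'
#' Missing values are rejected, not imputed: the estimation machinery assumes
#' a complete cohort, and silent imputation would change the estimand.
#'
#' @param y binary outcome vector (0/1).
#' @param a binary treatment vector (0/1); may be `NULL` when `dose` is
#'   supplied, in which case `a` is derived as `as.integer(dose > 0)`.
#' @param w numeric matrix or data frame of baseline covariates with column
#'   names, one row per subject.
#' @param dose optional non-negative total-dose vector.
#' @return An object of class `tl_cohort`: a list with elements `y`, `a`,
#'   `w` (numeric matrix), `dose` (or `NULL`) and `n`.
#' @examples
#' ch <- cohort(y = c(0, 1, 0), a = c(0, 1, 1),
#'              w = cbind(age = c(28, 33, 41), bmi = c(21, 24, 19)))
#' ch$n
#' @export
cohort <- function(y, a = NULL, w, dose = NULL) {
  if (is.data.frame(w)) w <- as.matrix(w)
  if (!is.matrix(w) || !is.numeric(w)) {
    stop("`w` must be a numeric matrix or data frame of baseline covariates",
         call. = FALSE)
  }
  if (is.null(colnames(w))) {
    stop("`w` must have column names", call. = FALSE)
  }
  if (is.null(a)) {
    if (is.null(dose)) {
      stop("supply `a`, or `dose` from which to derive it", call. = FALSE)
    }
    a <- as.integer(dose > 0)
  }
  obj <- structure(
    list(y = as.numeric(y), a = as.numeric(a), w = w,
         dose = if (is.null(dose)) NULL else as.numeric(dose),
         n = length(y)),
    class = "tl_cohort"
  )
  validate_cohort(obj)
}

validate_cohort <- function(x) {
  stopifnot(inherits(x, "tl_cohort"))
  n <- x$n
  miss <- list(y = which(is.na(x$y)), a = which(is.na(x$a)),
               w = which(apply(is.na(x$w), 1, any)))
  if (!is.null(x$dose)) miss$dose <- which(is.na(x$dose))
  bad <- miss[lengths(miss) > 0]
  if (length(bad)) {
    rows <- sort(unique(unlist(bad)))
    stop(sprintf("missing values are not allowed (rows: %s)",
                 paste(utils::head(rows, 10), collapse = ", ")),
         call. = FALSE)
  }
  if (!is_binary01(x$y)) {
    stop("outcome `y` must contain only 0/1", call. = FALSE)
  }
  if (!is_binary01(x$a)) {
    stop("treatment `a` must contain only 0/1", call. = FALSE)
  }
  if (length(x$a) != n || nrow(x$w) != n ||
      (!is.null(x$dose) && length(x$dose) != n)) {
    stop("y, a, w (and dose, if present) must share the same length n",
         call. = FALSE)
  }
  if (n < 1) stop("cohort must contain at least one subject", call. = FALSE)
  if (!is.null(x$dose)) {
    if (any(!is.finite(x$dose)) || any(x$dose < 0)) {
      stop("`dose` must be finite and non-negative", call. = FALSE)
    }
    if (!all((x$dose > 0) == (x$a == 1))) {
      stop("any-vs-none coding violated: need dose > 0 exactly when a = 1",
           call. = FALSE)
    }
  }
  x
}

#' @export
print.tl_cohort <- function(x, ...) {
  cat(sprintf("<tl_cohort> n = %d subjects\n", x$n))
  cat(sprintf("  treated: %d (%.1f%%), events: %d (%.1f%%)\n",
              sum(x$a), 100 * mean(x$a), sum(x$y), 100 * mean(x$y)))
  cat(sprintf("  covariates (%d): %s\n", ncol(x$w),
              paste(colnames(x$w), collapse = ", ")))
  if (!is.null(x$dose)) {
    cat(sprintf("  dose: present, range [%g, %g]\n",
                min(x$dose), max(x$dose)))
  }
  invisible(x)
}

#' Run configuration for the roadmap analysis
#'
#' Collects the analysis settings shared across modules: the effect scale and
#' its null value, the confidence level, the number of cross-validation folds
#' `V` for super learning, the propensity-score truncation bound (a number in
#' (0, 0.5) or `"auto"` for the sample-size formula, see
#' [resolve_ps_bound()]), the RNG seed, the cohort column roles, the
#' total-dose cut points, and the learner libraries.
#'
#' @param scale effect scale, one of `"RD"`, `"RR"`, `"OR"`.
#' @param level confidence level in (0, 1).
#' @param v_folds number of cross-validation folds `V` (default 20, chosen
#'   with event scarcity in mind).
#' @param ps_bound `"auto"` or a number in (0, 0.5).
#' @param seed integer RNG seed controlling folds and stochastic learners.
#' @param outcome_col,treatment_col,dose_col,covariate_cols column roles used
#'   by [read_cohort()]; `treatment_col`/`dose_col` may be `NULL`.
#' @param dose_cuts upper cut points of the positive dose groups; the default
#'   `c(0, 10, 20, 30, 40, 50)` yields the seven categories
#'   0, (0,10], (10,20], ..., (50, Inf).
#' @param outcome_library,ps_library character vectors of learner names (see
#'   [default_learner_library()]).
#' @param strict_positivity abort (rather than warn) on empty treated/control
#'   cells in the positivity tables.
#' @return An object of class `tl_run_config`.
#' @export
run_config <- function(scale = c("RD", "RR", "OR"),
                       level = 0.95,
                       v_folds = 20L,
                       ps_bound = "auto",
                       seed = 1L,
                       outcome_col = "y",
                       treatment_col = "a",
                       dose_col = NULL,
                       covariate_cols = NULL,
                       dose_cuts = c(0, 10, 20, 30, 40, 50),
                       outcome_library = c("logistic", "lasso", "bagged_trees"),
                       ps_library = c("logistic", "spline_gam", "bagged_trees"),
                       strict_positivity = FALSE) {
  scale <- match.arg(scale)
  stopifnot(is.numeric(level), length(level) == 1L, level > 0, level < 1)
  v_folds <- as.integer(v_folds)
  if (is.na(v_folds) || v_folds < 2L) {
    stop("`v_folds` must be an integer >= 2", call. = FALSE)
  }
  if (is.numeric(ps_bound)) {
    if (ps_bound <= 0 || ps_bound >= 0.5) {
      stop("numeric `ps_bound` must lie in (0, 0.5)", call. = FALSE)
    }
  } else if (!identical(ps_bound, "auto")) {
    stop('`ps_bound` must be "auto" or a number in (0, 0.5)', call. = FALSE)
  }
  structure(
    list(scale = scale,
         null_value = if (scale == "RD") 0 else 1,
         level = level,
         v_folds = v_folds,
         ps_bound = ps_bound,
         seed = as.integer(seed),
         outcome_col = outcome_col,
         treatment_col = treatment_col,
         dose_col = dose_col,
         covariate_cols = covariate_cols,
         dose_cuts = as.numeric(dose_cuts),
         outcome_library = outcome_library,
         ps_library = ps_library,
         strict_positivity = isTRUE(strict_positivity)),
    class = "tl_run_config"
  )
}

#' Read a run configuration from a YAML or JSON file
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are an error so
#' that typos do not silently fall back to defaults.
#'
#' @param path path to a YAML (or JSON; YAML is a superset) file.
#' @return A `tl_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  # YAML 1.1 reads an unquoted key `n:` as the boolean FALSE; restore it in
  # the simulate block, where a bare `n` is the natural cohort-size key
  if (!is.null(raw$simulate)) {
    names(raw$simulate)[names(raw$simulate) == "FALSE"] <- "n"
  }
  known <- names(formals(run_config))
  extra <- setdiff(names(raw), c(known, "simulate", "input", "output_dir"))
  if (length(extra)) {
    stop("unknown config keys: ", paste(extra, collapse = ", "), call. = FALSE)
  }
  cfg <- do.call(run_config, raw[intersect(names(raw), known)])
  attr(cfg, "simulate") <- raw$simulate
  attr(cfg, "input") <- raw$input
  attr(cfg, "output_dir") <- raw$output_dir
  cfg
}

#' Read a cohort CSV
#'
#' Reads a comma-separated file with a header row and assembles a validated
#' [cohort()] using the column roles declared in the run configuration.  When
#' no treatment column is configured (or present) but a dose column is, the
#' treatment indicator is derived by any-vs-none coding (`a = 1` iff
#' `dose > 0`).
#'
#' @param path CSV file path.
#' @param config a [run_config()] declaring `outcome_col`, `treatment_col`,
#'   `dose_col` and `covariate_cols`.
#' @return A validated `tl_cohort`.
#' @export
read_cohort <- function(path, config) {
  stopifnot(inherits(config, "tl_run_config"))
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  covs <- config$covariate_cols %||%
    setdiff(names(df), c(config$outcome_col, config$treatment_col,
                         config$dose_col))
  have_a <- !is.null(config$treatment_col) &&
    config$treatment_col %in% names(df)
  need <- c(config$outcome_col,
            if (have_a) config$treatment_col,
            config$dose_col, covs)
  absent <- setdiff(need, names(df))
  if (length(absent)) {
    stop("column(s) not found in ", path, ": ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (!have_a && is.null(config$dose_col)) {
    stop("neither a treatment column nor a dose column is configured",
         call. = FALSE)
  }
  w <- as.matrix(df[, covs, drop = FALSE])
  storage.mode(w) <- "double"
  cohort(y = df[[config$outcome_col]],
         a = if (have_a) df[[config$treatment_col]] else NULL,
         w = w,
         dose = if (!is.null(config$dose_col)) df[[config$dose_col]])
}

#' Write a cohort to CSV
#'
#' Emits the same comma-separated layout [read_cohort()] consumes, so that
#' write-then-read is the identity on valid cohorts.  Output is
#' deterministic: same cohort, same bytes.
#'
#' @param x a `tl_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "tl_cohort"))
  df <- data.frame(y = x$y, a = x$a, check.names = FALSE)
  if (!is.null(x$dose)) df$dose <- x$dose
  df <- cbind(df, as.data.frame(x$w, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Propensity-score truncation bound from the sample size
#'
#' TMLE requires the propensity score (and one minus it) to stay away from
#' zero.  With `bound = "auto"` the lower bound is set by the sample-size
#' rule \eqn{5 / (\sqrt{n} \, \ln n)}; a numeric `bound` is passed through
#' unchanged.  At `n = 225` the rule gives 0.0615..., i.e. 0.06 at two
#' decimals.
#'
#' @param n number of subjects (>= 2).
#' @param bound `"auto"` or a number in (0, 0.5).
#' @return The truncation bound, a number in (0, 0.5).
#' @examples
#' resolve_ps_bound(225)        # 0.0615...
#' resolve_ps_bound(100)        # 5 / (10 * log(100))
#' resolve_ps_bound(225, 0.025) # pass-through
#' @export
resolve_ps_bound <- function(n, bound = "auto") {
  stopifnot(is.numeric(n), length(n) == 1L)
  if (n < 2) stop("`n` must be at least 2", call. = FALSE)
  if (is.numeric(bound)) {
    if (bound <= 0 || bound >= 0.5) {
      stop("`bound` must lie in (0, 0.5)", call. = FALSE)
    }
    return(bound)
  }
  if (!identical(bound, "auto")) {
    stop('`bound` must be "auto" or numeric', call. = FALSE)
  }
  b <- 5 / (sqrt(n) * log(n))
  if (b <= 0 || b >= 0.5) {
    stop(sprintf(
      "automatic bound 5/(sqrt(n) ln n) = %.4f falls outside (0, 0.5) at n = %d; supply a numeric bound",
      b, as.integer(n)), call. = FALSE)
  }
  b
}
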