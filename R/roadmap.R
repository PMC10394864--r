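#' Published age-by-arm counts from the motivating ritodrine cohort
#'
#' The outcome-blind cross-tabulation of maternal age group against
#' treatment arm for the twin-pregnancy ritodrine cohort (n = 225), in the
#' original five-year groupings.  Two age groups contain no treated women,
#' the textbook positivity violation this package's diagnostics are built
#' around; [ritodrine_age_collapse()] gives the clinically coarser grouping
#' that removes it.
#'
#' @return A `tl_stratum_table` with seven age categories.
#' @export
ritodrine_age_table <- function() {
  path <- system.file("extdata", "ritodrine_age_groups.csv",
                      package = "tlroadmap", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$empty_treated <- df$treated == 0L
  df$empty_control <- df$control == 0L
  class(df) <- c("tl_stratum_table", "data.frame")
  df
}

#' @rdname ritodrine_age_table
#' @export
ritodrine_age_collapse <- function() {
  c("16-20" = "16-30", "21-25" = "16-30", "26-30" = "16-30",
    "31-35" = "31-35",
    "36-40" = "36-50", "41-45" = "36-50", "46-50" = "36-50")
}

# condition constructor for positivity-gated aborts (CLI exit code 3)
identifiability_error <- function(msg) {
  structure(class = c("tl_identifiability_error", "error", "condition"),
            list(message = msg, call = NULL))
}

bin_for_positivity <- function(x, max_levels = 6L) {
  u <- unique(x)
  if (length(u) <= max_levels) return(factor(x))
  q <- unique(stats::quantile(x, probs = seq(0, 1, length.out = 5L)))
  cut(x, breaks = q, include.lowest = TRUE)
}

#' Run the full Targeted Learning roadmap on a cohort
#'
#' Executes the roadmap stages in order: cohort summary, pre-fit
#' identifiability (positivity) diagnostics, targeted estimation with
#' post-fit propensity diagnostics, and the causal-gap sensitivity
#' analysis.  With `strict_positivity` set in the config, an empty
#' treated/control cell in any positivity table aborts before estimation
#' (condition class `tl_identifiability_error`); otherwise the flags are
#' recorded and estimation proceeds with propensity truncation.
#'
#' @param cohort a validated [cohort()], or `NULL` to read/simulate from
#'   `config` attributes (`input` CSV path, or `simulate` block).
#' @param config a [run_config()] (or path to a YAML config readable by
#'   [read_run_config()]).
#' @param output_dir optional directory; when given, the report and
#'   figure-backing tables are written there via [write_report()].
#' @return A `tl_roadmap_report` list with blocks `config`, `cohort`,
#'   `diagnostics`, `estimation`, `sensitivity`, `seed`, `versions`.
#' @export
run_roadmap <- function(cohort = NULL, config = run_config(),
                        output_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "tl_run_config"))
  truth <- NULL
  if (is.null(cohort)) {
    input <- attr(config, "input")
    simblock <- attr(config, "simulate")
    if (!is.null(input)) {
      cohort <- read_cohort(input, config)
    } else if (!is.null(simblock)) {
      sc <- do.call(sim_config, simblock)
      gen <- generate_cohort(sc)
      cohort <- gen$cohort
      truth <- gen$truth
    } else {
      stop("no cohort: supply one, or a config with `input` or `simulate`",
           call. = FALSE)
    }
  }
  validate_cohort(cohort)

  cohort_block <- list(n = cohort$n,
                       events = sum(cohort$y),
                       treated = sum(cohort$a),
                       control = sum(1 - cohort$a),
                       covariates = colnames(cohort$w),
                       has_dose = !is.null(cohort$dose))

  # --- identifiability diagnostics (outcome-blind) -------------------------
  pos_tables <- lapply(colnames(cohort$w), function(cn) {
    positivity_table(bin_for_positivity(cohort$w[, cn]), cohort$a)
  })
  names(pos_tables) <- colnames(cohort$w)
  flagged <- names(pos_tables)[vapply(pos_tables, function(t) {
    any(t$empty_treated | t$empty_control)
  }, TRUE)]
  if (length(flagged) && config$strict_positivity) {
    stop(identifiability_error(paste0(
      "positivity violation in covariate(s): ",
      paste(flagged, collapse = ", "),
      " (empty treated or control cells); estimation aborted in strict mode")))
  }
  diagnostics_block <- list(positivity_tables = pos_tables,
                            positivity_flags = flagged)
  if (!is.null(cohort$dose)) {
    diagnostics_block$dose_table <-
      crude_dose_proportions(cohort$dose, cohort$y, config$dose_cuts)
    diagnostics_block$dose_non_monotonic <-
      attr(diagnostics_block$dose_table, "non_monotonic")
  }

  # --- estimation ----------------------------------------------------------
  fit <- tmle_estimate(cohort, config)
  g <- fit$nuisances$g
  diagnostics_block$ps_cstat <- ps_cstat(g, cohort$a)
  diagnostics_block$ps_overlap <- ps_overlap_summary(g, cohort$a,
                                                     bound = fit$bound)
  estimation_block <- list(
    scale = fit$scale,
    psi1 = fit$psi1, psi0 = fit$psi0,
    estimate = fit$estimate, se = fit$se, ci = fit$ci,
    rd = fit$rd, se_rd = fit$se_rd, ci_rd = fit$ci_rd,
    epsilon = fit$epsilon,
    ps_bound = fit$bound,
    ps_bound_2dp = round(fit$bound, 2),
    mean_ic = mean(fit$ic),
    sl_outcome = list(
      weights = as.list(stats::setNames(
        fit$nuisances$sl_outcome$weights,
        vapply(fit$nuisances$sl_outcome$specs, `[[`, "", "name"))),
      cv_risks = as.list(fit$nuisances$sl_outcome$cv_risk_learners),
      failures = fit$nuisances$sl_outcome$failures),
    sl_ps = list(
      weights = as.list(stats::setNames(
        fit$nuisances$sl_ps$weights,
        vapply(fit$nuisances$sl_ps$specs, `[[`, "", "name"))),
      cv_risks = as.list(fit$nuisances$sl_ps$cv_risk_learners),
      failures = fit$nuisances$sl_ps$failures))
  if (!is.null(truth)) {
    estimation_block$sim_truth <- unclass(truth)
  }

  # --- sensitivity: on the estimation scale (log scale for RR/OR) ----------
  if (fit$scale == "RD") {
    sens <- causal_gap_scan(fit$estimate, fit$se, null = 0,
                            level = config$level)
  } else {
    sens <- causal_gap_scan(log(fit$estimate), fit$se, null = 0,
                            level = config$level)
  }

  report <- structure(
    list(config = unclass(config),
         cohort = cohort_block,
         diagnostics = diagnostics_block,
         estimation = estimation_block,
         sensitivity = sens,
         tmle = fit,
         seed = config$seed,
         versions = list(package = as.character(
           utils::packageVersion("tlroadmap")),
           r = R.version.string)),
    class = "tl_roadmap_report")
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' @export
print.tl_roadmap_report <- function(x, ...) {
  cat("<tl_roadmap_report>\n")
  cat(sprintf("  cohort: n = %d, events = %d, treated = %d\n",
              x$cohort$n, x$cohort$events, x$cohort$treated))
  if (length(x$diagnostics$positivity_flags)) {
    cat("  positivity flags:",
        paste(x$diagnostics$positivity_flags, collapse = ", "), "\n")
  } else {
    cat("  positivity: no empty cells flagged\n")
  }
  cat(sprintf("  PS C-statistic: %.3f; truncation no-op: %s\n",
              x$diagnostics$ps_cstat,
              isTRUE(x$diagnostics$ps_overlap$truncation_noop)))
  cat(sprintf("  %s = %.4f (se %.4f), %d%% CI [%.4f, %.4f]\n",
              x$estimation$scale, x$estimation$estimate, x$estimation$se,
              round(100 * x$config$level),
              x$estimation$ci[1], x$estimation$ci[2]))
  cat(sprintf("  G-value = %.4f (%.2f SE units)\n",
              x$sensitivity$g_value,
              x$sensitivity$g_value / x$sensitivity$sigma))
  invisible(x)
}

#' Write a roadmap report and its figure-backing tables
#'
#' Emits `report.json` (the structured report; no timestamps, so identical
#' runs produce identical bytes), `ic_values.csv` (per-subject influence
#' curve, for audit), `fig2_table.csv` (crude dose-group proportions, when a
#' dose is present), `fig3_table.csv` (propensity overlap histogram), and
#' `fig4_table.csv` (the causal-gap scan grid).
#'
#' @param report a `tl_roadmap_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "tl_roadmap_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json <- report
  json$tmle <- NULL
  json$diagnostics$positivity_tables <-
    lapply(json$diagnostics$positivity_tables, as.data.frame)
  json$sensitivity <- list(grid = report$sensitivity$grid,
                           g_value = report$sensitivity$g_value,
                           flip = report$sensitivity$flip,
                           psi = report$sensitivity$psi,
                           sigma = report$sensitivity$sigma,
                           null = report$sensitivity$null,
                           level = report$sensitivity$level)
  jsonlite::write_json(unclass(json), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  utils::write.csv(data.frame(ic = report$tmle$ic,
                              ic1 = report$tmle$ic1,
                              ic0 = report$tmle$ic0),
                   file.path(dir, "ic_values.csv"), row.names = FALSE)
  if (!is.null(report$diagnostics$dose_table)) {
    utils::write.csv(report$diagnostics$dose_table,
                     file.path(dir, "fig2_table.csv"), row.names = FALSE)
  }
  ov <- report$diagnostics$ps_overlap
  utils::write.csv(data.frame(bin_lower = ov$breaks[-length(ov$breaks)],
                              bin_upper = ov$breaks[-1],
                              prop_treated = ov$prop_treated,
                              prop_control = ov$prop_control),
                   file.path(dir, "fig3_table.csv"), row.names = FALSE)
  utils::write.csv(report$sensitivity$grid,
                   file.path(dir, "fig4_table.csv"), row.names = FALSE)
  invisible(dir)
}

#' Validate a roadmap report against the shipped schema
#'
#' The package ships a JSON-schema-style description of the report layout
#' (`inst/schema/report-schema.json`).  This checker verifies the required
#' blocks and fields are present with the right basic types.
#'
#' @param report a `tl_roadmap_report` or a parsed `report.json` list.
#' @return `TRUE` invisibly; errors describe the first violation found.
#' @export
validate_report <- function(report) {
  schema <- jsonlite::read_json(system.file("schema", "report-schema.json",
                                            package = "tlroadmap",
                                            mustWork = TRUE))
  check_block <- function(obj, spec, path) {
    for (nm in names(spec$required)) {
      if (is.null(obj[[nm]])) {
        stop(sprintf("report field missing: %s/%s", path, nm), call. = FALSE)
      }
      want <- spec$required[[nm]]
      if (is.character(want)) {
        ok <- switch(want,
                     number = is.numeric(obj[[nm]]) ||
                       (is.list(obj[[nm]]) && all(vapply(obj[[nm]],
                                                         is.numeric, TRUE))),
                     string = is.character(obj[[nm]]),
                     integer = is.numeric(obj[[nm]]),
                     array = is.list(obj[[nm]]) || is.vector(obj[[nm]]) ||
                       is.data.frame(obj[[nm]]),
                     object = is.list(obj[[nm]]),
                     TRUE)
        if (!ok) {
          stop(sprintf("report field %s/%s is not of type %s",
                       path, nm, want), call. = FALSE)
        }
      } else {
        check_block(obj[[nm]], want, paste0(path, "/", nm))
      }
    }
  }
  check_block(report, schema, "")
  invisible(TRUE)
}
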