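#' The G-value: smallest causal gap that negates the finding
#'
#' The causal gap \eqn{\delta = \psi^{stat} - \psi^{causal}} is the
#' discrepancy between the statistical estimand and the causal parameter
#' when a causal assumption fails.  The G-value is the smallest |gap| that
#' would change the study's qualitative conclusion — move the confidence
#' interval to include the null when it is excluded, or to exclude it when
#' the null lies inside:
#' \deqn{G = \min(|\psi - z\sigma - null|, |\psi + z\sigma - null|).}
#'
#' @param psi point estimate on the estimation scale (use the log scale for
#'   RR/OR, with `null = 0` there).
#' @param sigma standard error (> 0).
#' @param null null value (0 for a risk difference).
#' @param level confidence level; `z` is the exact normal quantile unless
#'   overridden.
#' @param z optional fixed quantile (set `z = 1.96` to reproduce printed
#'   two-decimal arithmetic exactly).
#' @return The G-value (non-negative).
#' @examples
#' g_value(0.21, 0.062, z = 1.96)  # 0.0885 at 4 decimals
#' @export
g_value <- function(psi, sigma, null = 0, level = 0.95, z = NULL) {
  if (!is.numeric(sigma) || sigma <= 0) {
    stop("`sigma` must be positive", call. = FALSE)
  }
  zq <- z_quantile(level, z)
  min(abs(psi - zq * sigma - null), abs(psi + zq * sigma - null))
}

#' Causal-gap values at which the conclusion flips
#'
#' Under the shift convention \eqn{\hat\psi_\delta = \hat\psi - \delta} (the
#' bias-corrected estimate when the gap is \eqn{\delta}), returns the signed
#' gap at which the nearer CI bound touches the null (`delta_nullify`, equal
#' in magnitude to the G-value) and the gap at which the whole interval has
#' crossed to the other side of the null (`delta_reverse`).
#'
#' @inheritParams g_value
#' @return List with `delta_nullify` and `delta_reverse`.  When the null is
#'   inside the interval, `delta_nullify` is the member of the
#'   sign-symmetric pair with the smaller magnitude and both members are
#'   returned as `delta_nullify_pair`.
#' @export
flip_thresholds <- function(psi, sigma, null = 0, level = 0.95, z = NULL) {
  if (!is.numeric(sigma) || sigma <= 0) {
    stop("`sigma` must be positive", call. = FALSE)
  }
  zq <- z_quantile(level, z)
  lo <- psi - zq * sigma
  hi <- psi + zq * sigma
  # shifted bound b - delta = null  <=>  delta = b - null
  d_lo <- lo - null
  d_hi <- hi - null
  nearer <- if (abs(d_lo) <= abs(d_hi)) d_lo else d_hi
  farther <- if (abs(d_lo) <= abs(d_hi)) d_hi else d_lo
  out <- list(delta_nullify = nearer, delta_reverse = farther)
  if (lo < null && null < hi) out$delta_nullify_pair <- c(d_lo, d_hi)
  out
}

#' Non-parametric causal-gap scan
#'
#' Shifts the point estimate and both CI bounds by each hypothesized causal
#' gap \eqn{\delta} on a grid, expresses each gap in SE units, and reports
#' the closed-form flip thresholds and G-value alongside.  At
#' \eqn{\delta = 0} the shifted quantities equal the original estimate and
#' interval.
#'
#' @inheritParams g_value
#' @param delta_grid hypothesized gaps; default 81 equally spaced points
#'   spanning +/- 4 SE units.
#' @return A `tl_sensitivity_result`: `grid` (data frame with `delta`,
#'   `se_units`, `estimate`, `lower`, `upper`, `ci_includes_null`),
#'   `g_value`, `flip` (from [flip_thresholds()]), `psi`, `sigma`, `null`,
#'   `level`, `z`.
#' @export
causal_gap_scan <- function(psi, sigma, null = 0, level = 0.95,
                            delta_grid = NULL, z = NULL) {
  if (!is.numeric(sigma) || sigma <= 0) {
    stop("`sigma` must be positive", call. = FALSE)
  }
  zq <- z_quantile(level, z)
  if (is.null(delta_grid)) {
    delta_grid <- seq(-4, 4, length.out = 81L) * sigma
  }
  grid <- data.frame(delta = delta_grid,
                     se_units = delta_grid / sigma,
                     estimate = psi - delta_grid,
                     lower = psi - zq * sigma - delta_grid,
                     upper = psi + zq * sigma - delta_grid)
  grid$ci_includes_null <- grid$lower <= null & null <= grid$upper
  structure(
    list(grid = grid,
         g_value = g_value(psi, sigma, null, level, z),
         flip = flip_thresholds(psi, sigma, null, level, z),
         psi = psi, sigma = sigma, null = null, level = level, z = zq),
    class = "tl_sensitivity_result")
}

#' @export
print.tl_sensitivity_result <- function(x, ...) {
  cat(sprintf("<tl_sensitivity_result> psi = %.4f, sigma = %.4f, null = %g\n",
              x$psi, x$sigma, x$null))
  cat(sprintf("  G-value = %.4f (%.2f SE units)\n",
              x$g_value, x$g_value / x$sigma))
  cat(sprintf("  gap nullifying the finding: %.4f; gap reversing it: %.4f\n",
              x$flip$delta_nullify, x$flip$delta_reverse))
  cat(sprintf("  scan over %d gaps in [%.4f, %.4f]\n",
              nrow(x$grid), min(x$grid$delta), max(x$grid$delta)))
  invisible(x)
}
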