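#' Stratified cross-validation folds
#'
#' Assigns each of `n` subjects to one of `V` folds.  When a binary stratum
#' vector is given (typically the outcome, to spread scarce events), folds
#' are balanced within each stratum; fold sizes differ by at most one both
#' overall and within each stratum.  Deterministic given the seed.
#'
#' @param n number of subjects.
#' @param v number of folds, `2 <= v <= n`.
#' @param strata optional vector defining strata (e.g. the outcome).
#' @param seed RNG seed.
#' @return Integer vector of fold ids in `1:v`, length `n`.
#' @export
make_folds <- function(n, v, strata = NULL, seed = 1L) {
  n <- as.integer(n); v <- as.integer(v)
  if (v < 2L) stop("need at least 2 folds", call. = FALSE)
  if (v > n) stop(sprintf("V = %d exceeds n = %d", v, n), call. = FALSE)
  if (is.null(strata)) strata <- rep(1L, n)
  stopifnot(length(strata) == n)
  with_seed(seed, {
    fold <- integer(n)
    count <- integer(v)  # current fold sizes, to balance across strata
    for (s in unique(sort(strata))) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      # deal cyclically over folds ordered by current size (ties shuffled)
      ord <- order(count + stats::runif(v) * 0.5)
      fold[idx] <- ord[((seq_along(idx) - 1L) %% v) + 1L]
      count <- tabulate(fold[fold > 0L], v)
    }
    fold
  })
}

#' Learner specifications for the super-learner library
#'
#' Four built-in learner families cover the roles of the usual
#' point-treatment libraries: `"logistic"` (unpenalized main-terms logistic
#' regression), `"lasso"` (L1-penalized logistic with the penalty chosen by
#' inner cross-validation on the training folds only), `"spline_gam"`
#' (additive logistic regression with a modest smooth basis per continuous
#' covariate), and `"bagged_trees"` (a probability random forest, the
#' flexible tree learner of the library).
#'
#' @param name learner family name.
#' @param ... hyperparameter overrides (`num_trees`, `min_node_size`, `k`
#'   basis dimension, `inner_folds`).
#' @return A `tl_learner_spec`.
#' @export
learner_spec <- function(name = c("logistic", "lasso", "spline_gam",
                                  "bagged_trees"), ...) {
  name <- match.arg(name)
  hyper <- utils::modifyList(
    switch(name,
           logistic = list(),
           lasso = list(inner_folds = 5L),
           spline_gam = list(k = 4L),
           bagged_trees = list(num_trees = 200L, min_node_size = 10L)),
    list(...))
  structure(list(name = name, hyperparameters = hyper),
            class = "tl_learner_spec")
}

#' @rdname learner_spec
#' @param names character vector of learner family names.
#' @export
default_learner_library <- function(names = c("logistic", "lasso",
                                              "spline_gam",
                                              "bagged_trees")) {
  lapply(names, learner_spec)
}

# ---- individual learner fit/predict ---------------------------------------

fit_learner <- function(spec, x, y, seed = 1L) {
  df <- as.data.frame(x)
  df$.y <- y
  fit <- switch(spec$name,
    logistic = {
      stats::glm(.y ~ ., data = df, family = stats::binomial())
    },
    lasso = {
      if (ncol(x) < 2L) {
        # glmnet needs >= 2 columns; an unpenalized fit fills the role
        stats::glm(.y ~ ., data = df, family = stats::binomial())
      } else {
        foldid <- make_folds(length(y), spec$hyperparameters$inner_folds,
                             strata = y, seed = seed)
        glmnet::cv.glmnet(as.matrix(x), y, family = "binomial",
                          foldid = foldid)
      }
    },
    spline_gam = {
      fm <- gam_formula(x, k = spec$hyperparameters$k)
      mgcv::gam(fm, data = df, family = stats::binomial())
    },
    bagged_trees = {
      df$.y <- factor(y, levels = c(0, 1))
      ranger::ranger(.y ~ ., data = df, probability = TRUE,
                     num.trees = spec$hyperparameters$num_trees,
                     min.node.size = spec$hyperparameters$min_node_size,
                     respect.unordered.factors = TRUE,
                     seed = seed, num.threads = 1L)
    },
    stop("unknown learner: ", spec$name, call. = FALSE))
  list(spec = spec, fit = fit, columns = colnames(x))
}

gam_formula <- function(x, k) {
  terms <- vapply(colnames(x), function(cn) {
    nu <- length(unique(x[, cn]))
    if (nu > 6) sprintf("s(`%s`, k = %d)", cn, max(3L, min(k, nu - 1L)))
    else sprintf("`%s`", cn)
  }, "")
  stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
}

predict_learner <- function(model, x) {
  df <- as.data.frame(x)
  p <- switch(model$spec$name,
    logistic = stats::predict(model$fit, newdata = df, type = "response"),
    lasso = {
      if (inherits(model$fit, "glm")) {
        stats::predict(model$fit, newdata = df, type = "response")
      } else {
        drop(stats::predict(model$fit, newx = as.matrix(x),
                            s = "lambda.min", type = "response"))
      }
    },
    spline_gam = as.numeric(stats::predict(model$fit, newdata = df,
                                           type = "response")),
    bagged_trees = stats::predict(model$fit, data = df,
                                  num.threads = 1L)$predictions[, "1"])
  clip(as.numeric(p), .PROB_EPS, 1 - .PROB_EPS)
}

# ---- ensemble --------------------------------------------------------------

neg_bernoulli_loglik <- function(p, y) {
  p <- clip(p, .PROB_EPS, 1 - .PROB_EPS)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Minimize CV risk of the convex combination over the weight simplex via a
# softmax parametrization (first coordinate pinned at 0), with every vertex
# checked so a single dominant learner is recovered exactly.
solve_simplex_weights <- function(cv_preds, y) {
  k <- ncol(cv_preds)
  risk_w <- function(w) neg_bernoulli_loglik(drop(cv_preds %*% w), y)
  if (k == 1L) {
    return(list(weights = 1, risk = risk_w(1)))
  }
  softmax <- function(b) {
    e <- exp(c(0, b) - max(c(0, b)))
    e / sum(e)
  }
  obj <- function(b) risk_w(softmax(b))
  if (k == 2L) {
    opt_par <- stats::optimize(function(b) obj(b), c(-30, 30),
                               tol = 1e-12)$minimum
  } else {
    opt <- stats::optim(rep(0, k - 1L), obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    # polish with Nelder-Mead in case BFGS stalled on a flat direction
    opt_par <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                            control = list(maxit = 2000,
                                           reltol = 1e-14))$par
  }
  best_w <- softmax(opt_par)
  best_r <- risk_w(best_w)
  for (j in seq_len(k)) {
    wj <- as.numeric(seq_len(k) == j)
    rj <- risk_w(wj)
    if (rj < best_r - 1e-12) {
      best_w <- wj
      best_r <- rj
    }
  }
  best_w <- pmax(best_w, 0)
  best_w <- best_w / sum(best_w)
  list(weights = best_w, risk = risk_w(best_w))
}

#' Fit a cross-validated super-learner ensemble
#'
#' Fits every learner of the library on each training fold, collects
#' out-of-fold probability predictions, and chooses convex combination
#' weights minimizing the cross-validated negative Bernoulli log-likelihood
#' over the simplex.  All learners are then refit on the full data for
#' prediction.  A learner that fails on a fold contributes the training-fold
#' event rate for that fold's predictions and the failure is logged in the
#' result; fitting never aborts because one library member errored.
#'
#' @param x numeric feature matrix (no missing values).
#' @param y binary response vector.
#' @param specs list of [learner_spec()]s (or character names).
#' @param v number of cross-validation folds.
#' @param seed RNG seed controlling folds and stochastic learners.
#' @return A `tl_super_learner` with weights, per-learner and ensemble CV
#'   risks, fold assignment, out-of-fold predictions, full-data fits and a
#'   failure log.
#' @export
fit_super_learner <- function(x, y, specs = default_learner_library(),
                              v = 20L, seed = 1L) {
  if (is.character(specs)) specs <- lapply(specs, learner_spec)
  specs <- lapply(specs, function(s) {
    if (inherits(s, "tl_learner_spec")) s else do.call(learner_spec, s)
  })
  x <- as.matrix(x)
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  }
  n <- length(y)
  stopifnot(nrow(x) == n, length(specs) >= 1L)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  if (!is_binary01(y)) stop("`y` must be binary 0/1", call. = FALSE)
  if (sum(y) == 0L || sum(1 - y) == 0L) {
    stop("response is constant (no events or no non-events)", call. = FALSE)
  }
  seeds <- child_seeds(seed, 2L + length(specs))
  folds <- make_folds(n, v, strata = y, seed = seeds[1])
  k <- length(specs)
  cv_preds <- matrix(NA_real_, n, k,
                     dimnames = list(NULL, vapply(specs, `[[`, "", "name")))
  failures <- character()
  for (vv in seq_len(v)) {
    tr <- folds != vv
    for (j in seq_len(k)) {
      pj <- tryCatch(
        predict_learner(
          fit_learner(specs[[j]], x[tr, , drop = FALSE], y[tr],
                      seed = seeds[2L + j]),
          x[!tr, , drop = FALSE]),
        error = function(e) {
          failures <<- c(failures,
                         sprintf("fold %d, learner %s: %s", vv,
                                 specs[[j]]$name, conditionMessage(e)))
          rep(clip(mean(y[tr]), .PROB_EPS, 1 - .PROB_EPS), sum(!tr))
        })
      cv_preds[!tr, j] <- pj
    }
  }
  learner_risks <- apply(cv_preds, 2, neg_bernoulli_loglik, y = y)
  sol <- solve_simplex_weights(cv_preds, y)
  full_fits <- vector("list", k)
  for (j in seq_len(k)) {
    full_fits[[j]] <- tryCatch(
      fit_learner(specs[[j]], x, y, seed = seeds[2L + j]),
      error = function(e) {
        failures <<- c(failures, sprintf("full data, learner %s: %s",
                                         specs[[j]]$name,
                                         conditionMessage(e)))
        list(spec = list(name = ".constant"),
             fit = clip(mean(y), .PROB_EPS, 1 - .PROB_EPS),
             columns = colnames(x))
      })
  }
  obj <- structure(
    list(specs = specs, weights = sol$weights,
         cv_risk_learners = learner_risks, cv_risk_ensemble = sol$risk,
         folds = folds, cv_preds = cv_preds, full_fits = full_fits,
         columns = colnames(x), failures = failures, seed = seed),
    class = "tl_super_learner")
  obj$fitted <- predict_proba(obj, x)
  obj
}

#' Predict ensemble probabilities
#'
#' @param fit a `tl_super_learner`.
#' @param x feature matrix with the training columns.
#' @return Probability vector in (0, 1): the weighted combination of the
#'   full-data learner predictions.
#' @export
predict_proba <- function(fit, x) {
  stopifnot(inherits(fit, "tl_super_learner"))
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- fit$columns[seq_len(ncol(x))]
  if (!identical(colnames(x), fit$columns)) {
    missing_cols <- setdiff(fit$columns, colnames(x))
    if (length(missing_cols)) {
      stop("prediction columns do not match training columns; missing: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    x <- x[, fit$columns, drop = FALSE]
  }
  p <- matrix(0, nrow(x), length(fit$full_fits))
  for (j in seq_along(fit$full_fits)) {
    if (fit$weights[j] == 0) next
    m <- fit$full_fits[[j]]
    p[, j] <- if (identical(m$spec$name, ".constant")) {
      rep(m$fit, nrow(x))
    } else {
      predict_learner(m, x)
    }
  }
  clip(drop(p %*% fit$weights), .PROB_EPS, 1 - .PROB_EPS)
}

#' @export
predict.tl_super_learner <- function(object, newdata, ...) {
  predict_proba(object, newdata)
}

#' @export
print.tl_super_learner <- function(x, ...) {
  cat("<tl_super_learner>\n")
  tab <- data.frame(learner = vapply(x$specs, `[[`, "", "name"),
                    weight = round(x$weights, 4),
                    cv_risk = round(x$cv_risk_learners, 6))
  print(tab, row.names = FALSE)
  cat(sprintf("ensemble CV risk: %.6f (%d folds)\n", x$cv_risk_ensemble,
              max(x$folds)))
  if (length(x$failures)) {
    cat(sprintf("learner failures logged: %d\n", length(x$failures)))
  }
  invisible(x)
}
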