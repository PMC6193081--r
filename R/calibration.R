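#' Sparse clinical series: cohort medians with median absolute errors
#'
#' One observable of one treatment branch: the cohort median and its
#' median absolute error (MAE) at sparse sampling times. A "series set" is
#' a plain list of these objects.
#'
#' @param branch `"placebo"` or `"bIAP"`.
#' @param observable `"AP"` (IU/L), `"IL6"` or `"IL10"` (pg/mL).
#' @param time_h Strictly increasing, non-negative sampling times (h).
#' @param median Cohort medians (clinical units), >= 0.
#' @param mae Median absolute errors, > 0, same length.
#' @return Object of class `clinical_series`.
#' @export
clinical_series <- function(branch, observable, time_h, median, mae) {
  branch <- match.arg(branch, c("placebo", "bIAP"))
  observable <- match.arg(observable, c("AP", "IL6", "IL10"))
  n <- length(time_h)
  if (n == 0) stop("series must contain at least one point", call. = FALSE)
  if (length(median) != n || length(mae) != n) {
    stop("time_h, median and mae must have equal length", call. = FALSE)
  }
  if (any(time_h < 0) || any(diff(time_h) <= 0)) {
    stop("times must be non-negative and strictly increasing", call. = FALSE)
  }
  if (any(median < 0)) stop("median values must be >= 0", call. = FALSE)
  if (any(mae <= 0)) stop("mae must be > 0", call. = FALSE)
  structure(list(branch = branch, observable = observable,
                 time_h = as.numeric(time_h), median = as.numeric(median),
                 mae = as.numeric(mae)),
            class = "clinical_series")
}

#' @export
print.clinical_series <- function(x, ...) {
  cat(sprintf("<clinical_series> %s / %s, %d points over [%g, %g] h\n",
              x$branch, x$observable, length(x$time_h), min(x$time_h),
              max(x$time_h)))
  invisible(x)
}

# Model prediction at the sampling times of a series, in clinical units.
.predict_series <- function(trajectory, series) {
  obs <- trajectory_observables(trajectory)
  stats::approx(obs$time_h, obs[[series$observable]],
                xout = series$time_h, rule = 2)$y
}

#' MAE-weighted least-squares loss
#'
#' Sum over all points of all series of
#' `((model - median) / mae)^2`, with model output converted to clinical
#' units before differencing. Integration failure yields `+Inf` with a
#' warning, so bounded optimizers can continue past pathological
#' parameter draws.
#'
#' @param params A [model_parameters()] object.
#' @param series_set List of [clinical_series()] (one branch).
#' @param protocol The branch's [treatment_protocol()].
#' @param insult Optional secondary insult shared by the runs.
#' @param ... Passed to [integrate_model()].
#' @return Scalar loss (>= 0, possibly `Inf`).
#' @export
series_loss <- function(params, series_set, protocol, insult = NULL, ...) {
  if (!length(series_set)) stop("empty series set", call. = FALSE)
  horizon <- max(vapply(series_set, function(s) max(s$time_h), numeric(1)))
  tr <- tryCatch(
    integrate_model(params, protocol, horizon = max(horizon, 1),
                    insult = insult, ...),
    error = function(e) {
      warning("integration failed during loss evaluation: ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
  if (is.null(tr)) return(Inf)
  sum(vapply(series_set, function(s) {
    pred <- .predict_series(tr, s)
    sum(((pred - s$median) / s$mae)^2)
  }, numeric(1)))
}

# Per-series weighted residual sums (same weighting as series_loss).
.residuals_by_series <- function(params, series_set, protocol,
                                 insult = NULL, ...) {
  horizon <- max(vapply(series_set, function(s) max(s$time_h), numeric(1)))
  tr <- integrate_model(params, protocol, horizon = max(horizon, 1),
                        insult = insult, ...)
  out <- vapply(series_set, function(s) {
    pred <- .predict_series(tr, s)
    sum(((pred - s$median) / s$mae)^2)
  }, numeric(1))
  names(out) <- vapply(series_set,
                       function(s) paste(s$branch, s$observable, sep = "_"),
                       character(1))
  out
}

# Map free parameters to/from the unconstrained optimizer scale
# (logit over the box bounds).
.to_unconstrained <- function(x, lo, hi) {
  p <- (x - lo) / (hi - lo)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  log(p / (1 - p))
}
.from_unconstrained <- function(z, lo, hi) lo + (hi - lo) / (1 + exp(-z))

#' Calibrate free parameters against clinical series
#'
#' Two-stage bounded search over the free parameters: a seeded
#' Latin-hypercube screening of the box bounds (the stochastic global
#' stage), followed by derivative-free local refinement (Nelder-Mead on a
#' logit-transformed scale so the bounds are respected; bounded Brent when
#' a single parameter is free). Deterministic
#' for a fixed seed; the final loss never exceeds the loss of the best
#' screened point.
#'
#' @param params A [model_parameters()] with at least one free parameter
#'   (see the `free` argument of [model_parameters()]), or pass `free`.
#' @param series_set List of [clinical_series()] for the fitted branch.
#' @param protocol The branch's [treatment_protocol()].
#' @param free Optional character vector overriding the free set.
#' @param seed Random seed (default 42).
#' @param n_global Latin-hypercube evaluations (default 2000).
#' @param n_local Maximum local-refinement evaluations (default 400).
#' @param insult Optional secondary insult.
#' @param ... Passed to the loss (solver settings).
#' @return Object of class `fit_result`: fitted `model_parameters`,
#'   per-series residuals, total `loss`, evaluation `trace`, and `seed`.
#' @export
fit_parameters <- function(params, series_set, protocol, free = NULL,
                           seed = 42, n_global = 2000, n_local = 400,
                           insult = NULL, ...) {
  if (!length(series_set)) stop("empty series set", call. = FALSE)
  if (!is.null(free)) {
    params$free[] <- FALSE
    params$free[free] <- TRUE
  }
  free_names <- names(params$free)[params$free]
  if (!length(free_names)) {
    stop("at least one free parameter is required", call. = FALSE)
  }
  lo <- params$lower[free_names]
  hi <- params$upper[free_names]
  if (any(!is.finite(lo)) || any(!is.finite(hi))) {
    stop("free-parameter bounds must be finite", call. = FALSE)
  }
  obj_x <- function(x) {
    series_loss(set_parameter_values(params, stats::setNames(x, free_names)),
                series_set, protocol, insult = insult, ...)
  }

  trace <- list()
  degenerate <- all(hi - lo <= 0)
  if (degenerate) {
    best_x <- lo
    best_loss <- obj_x(best_x)
  } else {
    set.seed(seed)
    k <- length(free_names)
    grid <- lhs::randomLHS(max(n_global, 2), k)
    cand <- t(t(grid) * (hi - lo) + lo)
    # always include the nominal values among the candidates
    cand <- rbind(params$values[free_names], cand)
    losses <- apply(cand, 1, obj_x)
    trace$global <- data.frame(cand, loss = losses)
    best_i <- which.min(losses)
    best_x <- cand[best_i, ]
    best_loss <- losses[best_i]
    if (n_local > 0 && is.finite(best_loss)) {
      span <- hi > lo
      if (sum(span) == 1) {
        # one-dimensional refinement: bounded Brent on the raw scale
        obj_1d <- function(xi) {
          x <- best_x
          x[span] <- xi
          obj_x(x)
        }
        opt <- stats::optim(best_x[span], obj_1d, method = "Brent",
                            lower = lo[span], upper = hi[span],
                            control = list(maxit = n_local))
        if (is.finite(opt$value) && opt$value <= best_loss) {
          best_x[span] <- opt$par
          best_loss <- opt$value
        }
      } else {
        z0 <- .to_unconstrained(best_x[span], lo[span], hi[span])
        obj_z <- function(z) {
          x <- best_x
          x[span] <- .from_unconstrained(z, lo[span], hi[span])
          obj_x(x)
        }
        opt <- stats::optim(z0, obj_z, method = "Nelder-Mead",
                            control = list(maxit = n_local,
                                           reltol = 1e-10))
        if (is.finite(opt$value) && opt$value <= best_loss) {
          best_x[span] <- .from_unconstrained(opt$par, lo[span], hi[span])
          best_loss <- opt$value
        }
      }
      trace$local <- opt[c("value", "counts", "convergence")]
    }
  }
  fitted <- set_parameter_values(params,
                                 stats::setNames(best_x, free_names))
  structure(
    list(params = fitted,
         free = free_names,
         residuals = .residuals_by_series(fitted, series_set, protocol,
                                          insult = insult, ...),
         loss = best_loss,
         trace = trace,
         seed = seed),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> loss %.6g; free: %s\n", x$loss,
              paste(x$free, collapse = ", ")))
  print(round(x$params$values[x$free], 6))
  invisible(x)
}

#' Cross-branch validation
#'
#' Simulates the validation branch with the parameters calibrated on the
#' other branch (the shared-rate assumption: both cohorts underwent the
#' same surgery, so kinetic rates are treatment-independent and only the
#' protocol differs), and returns the per-series MAE-weighted residual
#' sums.
#'
#' @param fit A `fit_result` (or bare `model_parameters`).
#' @param series_set Series of the validation branch.
#' @param protocol The validation branch's protocol.
#' @param insult Optional secondary insult.
#' @param ... Solver settings.
#' @return Named numeric vector of per-series weighted residual sums.
#' @export
cross_validate <- function(fit, series_set, protocol, insult = NULL, ...) {
  params <- if (inherits(fit, "fit_result")) fit$params else fit
  stopifnot(inherits(params, "model_parameters"))
  if (!length(series_set)) stop("empty series set", call. = FALSE)
  obs <- vapply(series_set, function(s) s$observable, character(1))
  if (!all(obs %in% c("AP", "IL6", "IL10"))) {
    stop("unknown observable in validation series", call. = FALSE)
  }
  .residuals_by_series(params, series_set, protocol, insult = insult, ...)
}
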