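# In-silico studies: branch comparison, induction ablation, secondary-insult
# scenario, dose scaling, and variance-based global sensitivity analysis.

.peak_of <- function(trajectory, variable) {
  max(trajectory$states[, variable])
}
.auc_of <- function(trajectory, variable) {
  t <- trajectory$times
  y <- trajectory$states[, variable]
  sum(diff(t) * (y[-1] + y[-length(y)]) / 2)
}

# One ordering assertion on peaks and AUCs: larger-branch value must not be
# below the smaller-branch value (ties allowed; margins reported).
.ordering <- function(name, hi, lo, hi_label, lo_label) {
  data.frame(
    assertion = name,
    larger = hi_label, smaller = lo_label,
    margin_peak = hi$peak - lo$peak,
    margin_auc = hi$auc - lo$auc,
    pass = hi$peak >= lo$peak && hi$auc >= lo$auc)
}
.measures <- function(trajectory, variable) {
  list(peak = .peak_of(trajectory, variable),
       auc = .auc_of(trajectory, variable))
}

#' Placebo vs supplemented-AP branch comparison
#'
#' Simulates both protocols under identical parameters and asserts the
#' protective-effect orderings: more necrotic neutrophils and
#' pro-inflammatory cytokine in the placebo arm, more apoptotic
#' neutrophils in the supplemented arm. Orderings are checked on peak
#' values and AUCs (curves may cross transiently).
#'
#' @param params A [model_parameters()] object.
#' @param protocols Named list with `placebo` and `bIAP` protocols.
#' @param insult Optional shared secondary insult.
#' @param ... Solver settings for [integrate_model()].
#' @return List with both trajectories, an `orderings` data frame
#'   (assertion, margins, pass) and the configuration hash.
#' @export
run_branch_comparison <- function(params,
                                  protocols = list(
                                    placebo = placebo_protocol(),
                                    bIAP = appired2_protocol()),
                                  insult = NULL, ...) {
  tr_p <- integrate_model(params, protocols$placebo, insult = insult, ...)
  tr_b <- integrate_model(params, protocols$bIAP, insult = insult, ...)
  orderings <- rbind(
    .ordering("necrotic_neutrophils_placebo_ge_bIAP",
              .measures(tr_p, "nd_n"), .measures(tr_b, "nd_n"),
              "placebo", "bIAP"),
    .ordering("apoptotic_neutrophils_bIAP_ge_placebo",
              .measures(tr_b, "nd_a"), .measures(tr_p, "nd_a"),
              "bIAP", "placebo"),
    .ordering("proinflammatory_placebo_ge_bIAP",
              .measures(tr_p, "ch"), .measures(tr_b, "ch"),
              "placebo", "bIAP"))
  list(placebo = tr_p, bIAP = tr_b, orderings = orderings,
       config_hash = config_hash(list(params$values,
                                      unlist(protocols$bIAP))))
}

#' Induction-ablation study
#'
#' The structural comparison behind the induction hypothesis: fit the
#' model \emph{without} the induction term on the placebo branch and use
#' it to predict the supplemented branch; fit the model \emph{with}
#' induction on the supplemented branch and predict the placebo branch.
#' If the data carry an induction signal, the ablated model's AP residual
#' on the supplemented branch must be far larger than the full model's.
#'
#' @param series_set Full series set (both branches, as produced by
#'   [generate_clinical_series()]).
#' @param protocols Named list with `placebo` and `bIAP` protocols.
#' @param params Starting [model_parameters()].
#' @param free Free-parameter set for both fits (default: induction
#'   triple plus supplemented-AP clearance and binding).
#' @param seed,n_global,n_local Optimizer settings (see
#'   [fit_parameters()]).
#' @param ... Solver settings.
#' @return List with both `fit_result`s, the cross-branch AP residuals,
#'   the residual ratio `ablated_over_full` (bIAP AP residual of the
#'   ablated model over the full model's own bIAP AP residual), and the
#'   configuration hash.
#' @export
run_ablation_study <- function(series_set, protocols,
                               params = model_parameters(),
                               free = c("r_induce_peak", "r_induce",
                                        "t_ap_delay"),
                               seed = 42, n_global = 200, n_local = 150,
                               ...) {
  pick <- function(branch) {
    series_set[vapply(series_set, function(s) s$branch == branch,
                      logical(1))]
  }
  bIAP_series <- pick("bIAP")
  placebo_series <- pick("placebo")
  if (!length(bIAP_series) || !length(placebo_series)) {
    stop("both branches are required", call. = FALSE)
  }
  ap_only <- function(set) {
    set[vapply(set, function(s) s$observable == "AP", logical(1))]
  }

  # full model: calibrate on the supplemented branch, predict placebo
  full_fit <- fit_parameters(params, bIAP_series, protocols$bIAP,
                             free = free, seed = seed,
                             n_global = n_global, n_local = n_local, ...)
  full_placebo <- cross_validate(full_fit, placebo_series,
                                 protocols$placebo, ...)

  # ablated model: no induction term; calibrate on placebo, predict bIAP
  abl_params <- params
  abl_params$induction_enabled <- FALSE
  abl_free <- setdiff(free, c("r_induce_peak", "r_induce", "t_ap_delay"))
  if (!length(abl_free)) abl_free <- c("k_ap_deg_blood", "k_denovo_boost")
  abl_fit <- fit_parameters(abl_params, placebo_series, protocols$placebo,
                            free = abl_free, seed = seed,
                            n_global = n_global, n_local = n_local, ...)
  abl_bIAP <- cross_validate(abl_fit, bIAP_series, protocols$bIAP, ...)

  ap_res_full <- sum(full_fit$residuals[grep("_AP$",
                                             names(full_fit$residuals))])
  ap_res_abl <- sum(abl_bIAP[grep("_AP$", names(abl_bIAP))])
  list(
    full_fit = full_fit,
    ablated_fit = abl_fit,
    full_bIAP_ap_residual = ap_res_full,
    ablated_bIAP_ap_residual = ap_res_abl,
    ablated_over_full = ap_res_abl / max(ap_res_full, .Machine$double.eps),
    full_placebo_residuals = full_placebo,
    ablated_bIAP_residuals = abl_bIAP,
    config_hash = config_hash(list(params$values, seed = seed)))
}

#' Secondary-insult (excess-ITM) experiment
#'
#' Adds a secondary ITM source to both arms and asserts the protective
#' orderings seen under complications: in the supplemented arm, more
#' apoptotic neutrophils and anti-inflammatory cytokine; in the placebo
#' arm, more necrotic neutrophils and pro-inflammatory cytokine.
#'
#' @param params A [model_parameters()] object.
#' @param protocols Named list with `placebo` and `bIAP` protocols.
#' @param insult A `secondary_insult` with positive amplitude (from
#'   [generate_secondary_insult()]).
#' @param ... Solver settings.
#' @return List with trajectories, `orderings` data frame, and hash.
#' @export
run_excess_itm_experiment <- function(params,
                                      protocols = list(
                                        placebo = placebo_protocol(),
                                        bIAP = appired2_protocol()),
                                      insult, ...) {
  stopifnot(inherits(insult, "secondary_insult"))
  if (insult$amplitude <= 0) {
    stop("insult amplitude must be > 0", call. = FALSE)
  }
  tr_p <- integrate_model(params, protocols$placebo, insult = insult, ...)
  tr_b <- integrate_model(params, protocols$bIAP, insult = insult, ...)
  orderings <- rbind(
    .ordering("apoptotic_neutrophils_bIAP_ge_placebo",
              .measures(tr_b, "nd_a"), .measures(tr_p, "nd_a"),
              "bIAP", "placebo"),
    .ordering("necrotic_neutrophils_placebo_ge_bIAP",
              .measures(tr_p, "nd_n"), .measures(tr_b, "nd_n"),
              "placebo", "bIAP"),
    .ordering("proinflammatory_placebo_ge_bIAP",
              .measures(tr_p, "ch"), .measures(tr_b, "ch"),
              "placebo", "bIAP"),
    .ordering("antiinflammatory_bIAP_ge_placebo",
              .measures(tr_b, "ach"), .measures(tr_p, "ach"),
              "bIAP", "placebo"))
  list(placebo = tr_p, bIAP = tr_b, orderings = orderings,
       config_hash = config_hash(list(params$values, unlist(insult))))
}

#' Dose-scaling experiment
#'
#' Simulates the supplementation protocol at increasing regimen scales
#' (1x, 2x, 3x by default) under a shared secondary insult and asserts
#' monotone protection: peak/AUC of blood ITM, tissue ITM, necrotic
#' neutrophils and pro-inflammatory cytokine non-increasing in dose;
#' apoptotic neutrophils and anti-inflammatory cytokine non-decreasing.
#'
#' @param params A [model_parameters()] object.
#' @param base_protocol Protocol scaled by each element of `scales`.
#' @param scales Non-decreasing regimen scales (default 1, 2, 3).
#' @param insult Optional shared secondary insult.
#' @param ... Solver settings.
#' @return List with per-scale trajectories, a `monotonicity` data frame
#'   (variable, direction, peaks, pass), and hash.
#' @export
run_dose_scaling <- function(params, base_protocol = appired2_protocol(),
                             scales = c(1, 2, 3), insult = NULL, ...) {
  if (any(diff(scales) < 0)) {
    stop("scales must be non-decreasing", call. = FALSE)
  }
  runs <- lapply(scales, function(sc) {
    integrate_model(params, scale_protocol(base_protocol, sc),
                    insult = insult, ...)
  })
  names(runs) <- paste0("scale_", scales)
  chains <- list(
    itm_blood = "non-increasing", itm_tissue = "non-increasing",
    nd_n = "non-increasing", ch = "non-increasing",
    nd_a = "non-decreasing", ach = "non-decreasing")
  mono <- do.call(rbind, lapply(names(chains), function(vn) {
    peaks <- vapply(runs, .peak_of, numeric(1), variable = vn)
    aucs <- vapply(runs, .auc_of, numeric(1), variable = vn)
    ok <- if (chains[[vn]] == "non-increasing") {
      all(diff(peaks) <= 0) && all(diff(aucs) <= 0)
    } else {
      all(diff(peaks) >= 0) && all(diff(aucs) >= 0)
    }
    data.frame(variable = vn, direction = chains[[vn]],
               peaks = paste(signif(peaks, 6), collapse = " "),
               pass = ok)
  }))
  list(runs = runs, scales = scales, monotonicity = mono,
       config_hash = config_hash(list(params$values, scales = scales)))
}

#' Saltelli design and Sobol variance-based indices
#'
#' Generates the Saltelli cross-sampling design (A, B and the k
#' radial-substitution matrices AB_i) over uniform parameter ranges,
#' evaluates the model, and estimates first-order indices (Saltelli 2010
#' estimator) and total-order indices (Jansen estimator), with bootstrap
#' confidence intervals over the base samples.
#'
#' @param model Function taking a named numeric vector of inputs and
#'   returning a single numeric output.
#' @param ranges Named list of `c(lower, upper)` ranges.
#' @param n_samples Base sample count (>= 64 recommended); total model
#'   evaluations are `n_samples * (k + 2)`.
#' @param seed RNG seed.
#' @param n_boot Bootstrap replicates for the confidence intervals.
#' @param conf Confidence level (default 0.95).
#' @return Data frame with one row per parameter: `first_order`,
#'   `total`, and bootstrap CI bounds for each.
#' @export
sobol_indices <- function(model, ranges, n_samples = 256, seed = 1,
                          n_boot = 200, conf = 0.95) {
  k <- length(ranges)
  nms <- names(ranges)
  if (is.null(nms) || any(!nzchar(nms))) {
    stop("ranges must be a named list", call. = FALSE)
  }
  set.seed(seed)
  scale_row <- function(u) {
    vapply(seq_len(k),
           function(j) ranges[[j]][1] + u[j] * diff(ranges[[j]]),
           numeric(1))
  }
  A <- lhs::randomLHS(n_samples, k)
  B <- lhs::randomLHS(n_samples, k)
  eval_mat <- function(M) {
    apply(M, 1, function(u) {
      x <- stats::setNames(scale_row(u), nms)
      model(x)
    })
  }
  fA <- eval_mat(A)
  fB <- eval_mat(B)
  n_fail <- sum(!is.finite(fA)) + sum(!is.finite(fB))
  fAB <- matrix(NA_real_, n_samples, k)
  for (i in seq_len(k)) {
    ABi <- A
    ABi[, i] <- B[, i]
    fAB[, i] <- eval_mat(ABi)
    n_fail <- n_fail + sum(!is.finite(fAB[, i]))
  }
  n_total <- n_samples * (k + 2)
  if (n_fail / n_total > 0.05) {
    stop(sprintf("sensitivity analysis aborted: %.1f%% model failures",
                 100 * n_fail / n_total), call. = FALSE)
  }
  est <- function(idx) {
    fa <- fA[idx]; fb <- fB[idx]
    # centring removes the mean^2 term from the first-order estimator's
    # Monte-Carlo variance
    m <- mean(c(fa, fb), na.rm = TRUE)
    fa <- fa - m; fb <- fb - m
    v <- stats::var(c(fa, fb))
    if (!is.finite(v) || v <= 0) {
      return(list(S = rep(0, k), T = rep(0, k)))
    }
    S <- vapply(seq_len(k), function(i) {
      mean(fb * ((fAB[idx, i] - m) - fa), na.rm = TRUE) / v
    }, numeric(1))
    T <- vapply(seq_len(k), function(i) {
      0.5 * mean((fa - (fAB[idx, i] - m))^2, na.rm = TRUE) / v
    }, numeric(1))
    list(S = S, T = T)
  }
  point <- est(seq_len(n_samples))
  boots_S <- matrix(NA_real_, n_boot, k)
  boots_T <- matrix(NA_real_, n_boot, k)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n_samples, replace = TRUE)
    eb <- est(idx)
    boots_S[b, ] <- eb$S
    boots_T[b, ] <- eb$T
  }
  alpha <- (1 - conf) / 2
  data.frame(
    parameter = nms,
    first_order = point$S,
    first_order_lo = apply(boots_S, 2, stats::quantile, probs = alpha),
    first_order_hi = apply(boots_S, 2, stats::quantile, probs = 1 - alpha),
    total = point$T,
    total_lo = apply(boots_T, 2, stats::quantile, probs = alpha),
    total_hi = apply(boots_T, 2, stats::quantile, probs = 1 - alpha),
    n_failures = n_fail,
    row.names = NULL)
}

# Default sensitivity outputs: the inflammation-intensity summaries the
# model's conclusions rest on.
.sensitivity_outputs <- function(trajectory) {
  ap <- trajectory$states[, "ap_endo_blood"] +
    trajectory$states[, "ap_supp_blood"]
  post <- trajectory$times > 0.25
  c(peak_ch = .peak_of(trajectory, "ch"),
    auc_itm_tissue = .auc_of(trajectory, "itm_tissue"),
    peak_nd_n = .peak_of(trajectory, "nd_n"),
    trough_ap_blood = min(ap[post]))
}

#' Global sensitivity analysis of the inflammation model
#'
#' Variance-based (Sobol) sensitivity of the model's headline outputs --
#' peak pro-inflammatory cytokine, tissue-ITM AUC, peak necrotic
#' neutrophils, and the blood-AP trough -- to selected parameters varied
#' uniformly over ranges (default: each parameter's calibration bounds).
#'
#' @param params A [model_parameters()] object.
#' @param vary Character vector of parameter names to vary.
#' @param ranges Optional named list of `c(lower, upper)` overriding the
#'   stored bounds.
#' @param protocol Protocol for the runs (default supplemented arm).
#' @param n_samples Base Saltelli sample count (>= 64).
#' @param seed RNG seed.
#' @param horizon Simulation horizon (h).
#' @param ... Passed to [sobol_indices()] (e.g. `n_boot`).
#' @return Named list of data frames, one per output, as returned by
#'   [sobol_indices()].
#' @export
sensitivity_analysis <- function(params, vary, ranges = NULL,
                                 protocol = appired2_protocol(),
                                 n_samples = 64, seed = 1, horizon = 36,
                                 ...) {
  if (n_samples < 64) stop("n_samples must be >= 64", call. = FALSE)
  if (is.null(ranges)) {
    ranges <- lapply(vary, function(nm) {
      c(params$lower[[nm]], params$upper[[nm]])
    })
    names(ranges) <- vary
  }
  cache <- new.env(parent = emptyenv())
  run_outputs <- function(x) {
    key <- paste(sprintf("%.15g", x), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    out <- tryCatch({
      pp <- set_parameter_values(params, x)
      .sensitivity_outputs(
        integrate_model(pp, protocol, horizon = horizon, grid_h = 1 / 6))
    }, error = function(e) {
      stats::setNames(rep(NA_real_, 4),
                      c("peak_ch", "auc_itm_tissue", "peak_nd_n",
                        "trough_ap_blood"))
    })
    cache[[key]] <- out
    out
  }
  outputs <- c("peak_ch", "auc_itm_tissue", "peak_nd_n", "trough_ap_blood")
  res <- lapply(outputs, function(ob) {
    sobol_indices(function(x) run_outputs(x)[[ob]], ranges,
                  n_samples = n_samples, seed = seed, ...)
  })
  names(res) <- outputs
  res
}
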