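#' State variable names of the three-compartment model
#'
#' Blood: free inflammation-triggering moieties (ITM), endogenous and
#' supplemented AP, ITM-AP complexes awaiting Kupffer clearance, resting
#' neutrophils, pro- and anti-inflammatory cytokines, and the bolus depot.
#' Tissue: ITM, endogenous and supplemented AP, resting/activated
#' macrophages, activated/apoptotic/necrotic neutrophils, the damage
#' mediator D, and a three-stage linear chain that low-pass filters the
#' tissue ITM signal (the delayed inflammation drive for necrosis and
#' cytokine production). Liver: the releasable AP store (IU-equivalents).
#'
#' @return Character vector of state names, in canonical order.
#' @export
state_names <- function() {
  c("itm_blood", "itm_tissue",
    "ap_endo_blood", "ap_endo_tissue",
    "ap_supp_blood", "ap_supp_tissue",
    "itm_ap_blood",
    "m_r", "m_a",
    "n_r", "n_a", "nd_a", "nd_n",
    "ch", "ach", "d",
    "liver_store", "bolus_depot",
    "delay1", "delay2", "delay3")
}

# Kinetic parameter table: name = c(value, lower, upper).
# Units: first-order rates 1/h; bimolecular rates mm3/(molecule h) or
# mm3/(cell h); per-cell secretion rates molecules/(cell h); half-saturation
# constants molecules/mm3; pools IU; times h.
.param_table <- function() {
  list(
    # surgical insult (initial blood ITM load)
    itm_insult        = c(5e11, 0, 5e12),
    # ITM kinetics
    k_itm_deg_blood   = c(0.15, 0.015, 1.5),      # blood ITM degradation
    k_itm_bt          = c(0.40, 0.04, 4),      # blood->tissue transport (x permeability)
    k_itm_deg_tissue  = c(0.12, 0.012, 1.2),
    k_bind            = c(1e-11, 1e-12, 1e-10),  # ITM + AP -> complex (blood)
    k_deph            = c(3.0e-9, 3e-10, 3e-8),        # tissue dephosphorylation by AP
    k_phag_na         = c(1e-4, 1e-5, 1e-3),   # ITM phagocytosis by activated neutrophils
    k_phag_ma         = c(1e-5, 1e-6, 1e-4),   # ITM phagocytosis by activated macrophages
    k_itm_release     = c(2e6, 2e5, 2e7),      # ITM released per necrotic neutrophil
    k_kupffer         = c(2, 0.2, 20),         # Kupffer clearance of ITM-AP complexes
    # AP kinetics
    ap_baseline_iul   = c(50, 20, 120),        # homeostatic blood AP (IU/L)
    k_ap_deg_blood    = c(0.10, 0.01, 1),
    k_aps_deg_blood   = c(10, 1, 100),         # supplemented (bovine) AP blood clearance
    k_ap_bt           = c(0.02, 0.002, 0.2),   # fenestral blood->tissue transport (x permeability)
    k_ap_deg_tissue   = c(0.10, 0.01, 1),
    # liver
    liver_capacity_iu = c(5300, 1000, 10000),
    k_liver_flush     = c(25, 20, 100),        # distress-triggered store release
    h_liver_itm       = c(1e8, 1e7, 1e9),      # half-sat of the distress switch
    k_liver_restock   = c(0.05, 0.005, 0.5),
    t_liver_recovery  = c(2.0, 0.5, 6),        # de novo recovery midpoint (h)
    k_liver_recovery  = c(2.5, 0.5, 10),       # recovery switch steepness (1/h)
    k_denovo_boost    = c(4, 0, 30),           # deficit-driven de novo up-regulation
    # induction of endogenous AP by supplemented AP
    r_induce_peak     = c(1.8, 0, 6),
    r_induce          = c(0.35, 0.035, 3.5),
    t_ap_delay        = c(1.0, 0, 6),
    # endothelial permeability
    perm_max          = c(9, 1, 30),           # max fold-increase above baseline
    h_perm            = c(1e6, 1e5, 1e7),      # CH half-saturation
    # macrophages
    m_r0              = c(500, 100, 2000),
    k_mr_act          = c(5e-10, 5e-11, 5e-9),
    k_mr_death        = c(0.01, 0.001, 0.1),
    k_ma_death        = c(0.05, 0.005, 0.5),
    # neutrophils
    n_r0              = c(4000, 1000, 8000),
    k_nr_death        = c(0.04, 0.004, 0.4),
    k_diaped          = c(0.05, 0.005, 0.5),   # per unit excess permeability
    k_na_apop         = c(0.10, 0.01, 1),
    k_na_nec_max      = c(0.20, 0.02, 2),
    k_na_nec_min      = c(0.005, 0, 0.05),
    h_nec             = c(1e11, 1e10, 1e12),
    k_phag_nda        = c(2e-4, 2e-5, 2e-3),
    k_phag_ndn        = c(5e-5, 5e-6, 5e-4),
    k_nda_deg         = c(0.05, 0.005, 0.5),
    k_ndn_deg         = c(0.05, 0.005, 0.5),
    # cytokines
    ch0_pgml          = c(1, 0.1, 10),
    ach0_pgml         = c(2, 0.2, 20),
    k_ch_ma           = c(4e3, 4e2, 4e4),
    k_ch_ndn          = c(2e4, 2e3, 2e5),
    h_ch_delay        = c(1e10, 1e9, 1e11),
    h_ach_inh         = c(1e6, 1e5, 1e7),
    k_ch_deg          = c(0.40, 0.04, 4),
    k_ach_deg         = c(0.30, 0.03, 3),
    k_ach_ma          = c(2e2, 2e1, 2e3),
    k_ach_phag        = c(2e4, 2e3, 2e5),
    # damage mediator D
    k_d_ndn           = c(10, 1, 100),
    k_d_itm           = c(1e-3, 1e-4, 1e-2),
    k_d_deg           = c(0.02, 0.002, 0.2),
    # delayed inflammation drive (Erlang chain, mean lag tau_delay)
    tau_delay         = c(6, 1, 24),
    # bolus depot emptying (fast first-order, ~0.05 h transfer window)
    k_bolus           = c(100, 20, 500)
  )
}

#' Kinetic parameters of the inflammation model
#'
#' Builds the full parameter set: every kinetic rate, half-saturation
#' constant and pool size of the blood-tissue-liver system, each with a
#' nominal value, box bounds and a free/fixed flag for calibration, plus
#' the induction-term switch. Values default to the package's nominal
#' table; any subset can be overridden by name.
#'
#' @param ... Named scalar overrides of nominal values, e.g.
#'   `model_parameters(r_induce_peak = 0.2)`.
#' @param free Character vector of parameter names to mark free for
#'   calibration (default: none).
#' @param induction_enabled Logical; `FALSE` forces the induction term to
#'   zero identically (model ablation).
#' @return Object of class `model_parameters`: list with named numeric
#'   `values`, `lower`, `upper`, logical `free`, and `induction_enabled`.
#' @export
#' @examples
#' p <- model_parameters(free = c("r_induce_peak", "r_induce", "t_ap_delay"))
#' p$values[["t_ap_delay"]]
model_parameters <- function(..., free = character(),
                             induction_enabled = TRUE) {
  tab <- .param_table()
  values <- vapply(tab, `[`, numeric(1), 1L)
  lower <- vapply(tab, `[`, numeric(1), 2L)
  upper <- vapply(tab, `[`, numeric(1), 3L)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(values))
    if (length(bad)) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    for (nm in names(over)) {
      v <- over[[nm]]
      if (!is.finite(v) || v < 0) {
        stop("parameter ", nm, " must be finite and non-negative",
             call. = FALSE)
      }
      values[[nm]] <- v
      # keep bounds containing the overridden value
      lower[[nm]] <- min(lower[[nm]], v)
      upper[[nm]] <- max(upper[[nm]], v)
    }
  }
  bad_free <- setdiff(free, names(values))
  if (length(bad_free)) {
    stop("unknown free parameter(s): ", paste(bad_free, collapse = ", "),
         call. = FALSE)
  }
  p <- structure(
    list(values = values, lower = lower, upper = upper,
         free = stats::setNames(names(values) %in% free, names(values)),
         induction_enabled = isTRUE(induction_enabled)),
    class = "model_parameters")
  validate_parameters(p)
  p
}

#' Validate a parameter set
#'
#' Checks non-negativity of every rate and that each bound interval
#' contains its nominal value.
#'
#' @param params A `model_parameters` object.
#' @return The object, invisibly; error on violation.
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "model_parameters"))
  v <- params$values
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("all parameter values must be finite and non-negative",
         call. = FALSE)
  }
  if (any(params$lower > v + 1e-12) || any(params$upper < v - 1e-12)) {
    bad <- names(v)[params$lower > v | params$upper < v]
    stop("bounds exclude nominal value for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(params)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat(sprintf("<model_parameters> %d parameters (%d free), induction %s\n",
              length(x$values), sum(x$free),
              if (x$induction_enabled) "enabled" else "disabled"))
  invisible(x)
}

#' Update parameter values by name
#' @param params A `model_parameters` object.
#' @param values Named numeric vector of replacements.
#' @return Updated `model_parameters`.
#' @export
set_parameter_values <- function(params, values) {
  stopifnot(inherits(params, "model_parameters"))
  bad <- setdiff(names(values), names(params$values))
  if (length(bad)) {
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  params$values[names(values)] <- values
  validate_parameters(params)
}

#' Induction-term parameters of a parameter set
#'
#' @param params A `model_parameters` object.
#' @return List with `r_induce_peak` (1/h), `r_induce` (1/h),
#'   `t_ap_delay` (h) and `enabled`.
#' @export
induction_parameters <- function(params) {
  stopifnot(inherits(params, "model_parameters"))
  v <- params$values
  list(r_induce_peak = v[["r_induce_peak"]],
       r_induce = v[["r_induce"]],
       t_ap_delay = v[["t_ap_delay"]],
       enabled = params$induction_enabled)
}

#' Homeostatic (pre-insult) state
#'
#' The resting fixed point of the system: baseline AP and cytokine levels,
#' resting cell populations at their turnover equilibria, liver store at
#' capacity, and every inflammation-specific pool at zero.
#'
#' @param params A `model_parameters` object.
#' @return Named numeric state vector (see [state_names()]).
#' @export
homeostatic_state <- function(params) {
  stopifnot(inherits(params, "model_parameters"))
  v <- params$values
  uc <- unit_constants()
  s <- stats::setNames(numeric(length(state_names())), state_names())
  ap0 <- v[["ap_baseline_iul"]] * uc$ap_iu_per_l_to_molec_mm3
  mu0 <- endothelial_permeability(
    v[["ch0_pgml"]] * uc$cytokine_pg_ml_to_molec_mm3, params)
  s[["ap_endo_blood"]] <- ap0
  # tissue AP equilibrium: fenestral inflow balances tissue degradation
  s[["ap_endo_tissue"]] <-
    mu0 * v[["k_ap_bt"]] * ap0 * uc$rho_blood_tissue / v[["k_ap_deg_tissue"]]
  s[["m_r"]] <- v[["m_r0"]]
  s[["n_r"]] <- v[["n_r0"]]
  s[["ch"]] <- v[["ch0_pgml"]] * uc$cytokine_pg_ml_to_molec_mm3
  s[["ach"]] <- v[["ach0_pgml"]] * uc$cytokine_pg_ml_to_molec_mm3
  s[["liver_store"]] <- v[["liver_capacity_iu"]]
  s
}

#' Initial state at surgery onset
#'
#' The homeostatic state plus the surgical ITM load in blood
#' (`itm_insult`) and the protocol's bolus in the delivery depot.
#'
#' @param params A `model_parameters` object.
#' @param protocol A [treatment_protocol()] (default placebo).
#' @return Named numeric state vector.
#' @export
initial_state <- function(params, protocol = placebo_protocol()) {
  s <- homeostatic_state(params)
  s[["itm_blood"]] <- params$values[["itm_insult"]]
  s[["bolus_depot"]] <- protocol$bolus_iu * protocol$scale
  s
}

#' Write / read a parameter set as a flat key-value text file
#'
#' One row per parameter with fields `name`, `value`, `lower`, `upper`,
#' `free`, plus a pseudo-row `induction_enabled`. Tab-separated, full
#' double precision; the round trip is lossless.
#'
#' @param params A `model_parameters` object.
#' @param path File path.
#' @return `write_parameters` returns `path` invisibly; `read_parameters`
#'   returns the reconstructed `model_parameters` object.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "model_parameters"))
  df <- data.frame(
    name = names(params$values),
    value = sprintf("%.17g", params$values),
    lower = sprintf("%.17g", params$lower),
    upper = sprintf("%.17g", params$upper),
    free = as.integer(params$free))
  df <- rbind(df, data.frame(
    name = "induction_enabled",
    value = as.character(as.integer(params$induction_enabled)),
    lower = "0", upper = "1", free = "0"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "numeric", "numeric",
                                         "numeric", "integer"))
  need <- c("name", "value", "lower", "upper", "free")
  if (!identical(names(df), need)) {
    stop("parameter file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ind <- df$name == "induction_enabled"
  enabled <- if (any(ind)) df$value[ind][1] > 0 else TRUE
  df <- df[!ind, ]
  p <- structure(
    list(values = stats::setNames(df$value, df$name),
         lower = stats::setNames(df$lower, df$name),
         upper = stats::setNames(df$upper, df$name),
         free = stats::setNames(df$free > 0, df$name),
         induction_enabled = enabled),
    class = "model_parameters")
  validate_parameters(p)
  p
}
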