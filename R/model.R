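#' Endogenous-AP induction rate driven by supplemented AP
#'
#' The induction of endogenous (liver-type, tissue-nonspecific) AP release
#' triggered by AP supplementation is modelled as a reverse sigmoid in
#' time, centred at `t_ap_delay` (the lag while the flushed liver
#' recuperates, nominally 1 h), multiplied by the total supplemented AP
#' concentration:
#' \deqn{\frac{r_{peak}}{1 + e^{r(t - t_{delay})}} (APs_{tissue} + APs_{blood})}
#'
#' @param t Time since surgery onset (h), >= 0.
#' @param induction List as returned by [induction_parameters()].
#' @param ap_supp_total Total supplemented AP, tissue + blood
#'   (molecules/mm3), >= 0.
#' @return Induction rate (molecules/mm3/h); 0 when disabled or when no
#'   supplemented AP is present.
#' @export
#' @examples
#' ip <- induction_parameters(model_parameters())
#' induction_rate(ip$t_ap_delay, ip, 1e8)  # half of r_induce_peak * 1e8
induction_rate <- function(t, induction, ap_supp_total) {
  if (any(ap_supp_total < 0)) {
    stop("ap_supp_total must be >= 0", call. = FALSE)
  }
  if (!isTRUE(induction$enabled)) return(0 * t * ap_supp_total)
  z <- induction$r_induce * (t - induction$t_ap_delay)
  # exp() overflow yields Inf and a clean 0 coefficient; guard the underflow
  coef <- induction$r_induce_peak / (1 + exp(pmin(z, 700)))
  coef * ap_supp_total
}

#' Endothelial permeability multiplier
#'
#' Pro-inflammatory cytokines open the endothelial barrier through a
#' saturating (Hill, n = 2) response. The multiplier is 1 at zero cytokine
#' (baseline fenestral transport) and saturates at `1 + perm_max`.
#'
#' @param ch Pro-inflammatory cytokine concentration (molecules/mm3), >= 0.
#'   Vectorised.
#' @param params A [model_parameters()] object.
#' @return Dimensionless permeability multiplier, >= 1.
#' @export
endothelial_permeability <- function(ch, params) {
  if (any(ch < 0)) stop("ch must be >= 0", call. = FALSE)
  v <- params$values
  # reciprocal Hill form stays finite for arbitrarily large ch
  1 + v[["perm_max"]] / (1 + (v[["h_perm"]] / ch)^2)
}

#' Apoptosis and necrosis fluxes of activated neutrophils
#'
#' Activated neutrophils die through two pathways: apoptosis (first-order,
#' anti-inflammatory) and necrosis (pro-inflammatory). The necrotic rate
#' rises with the inflammation drive, a blend of instantaneous tissue ITM
#' and its delayed (Erlang-filtered) signal, so intense unresolved
#' inflammation pushes neutrophils towards necrosis.
#'
#' @param state Named state vector (see [state_names()]).
#' @param params A [model_parameters()] object.
#' @return Named numeric: `apoptosis` and `necrosis` fluxes (cells/mm3/h).
#' @export
neutrophil_fate_fluxes <- function(state, params) {
  v <- params$values
  drive <- 0.5 * (state[["itm_tissue"]] + state[["delay3"]])
  sigma <- drive / (drive + v[["h_nec"]])
  c(apoptosis = v[["k_na_apop"]] * state[["n_a"]],
    necrosis = (v[["k_na_nec_min"]] + v[["k_na_nec_max"]] * sigma) *
      state[["n_a"]])
}

#' ITM source from necrotic neutrophils
#'
#' Necrotic neutrophils lyse and release their content, feeding ITMs back
#' into the tissue (the pro-inflammatory positive feedback). Linear in the
#' necrotic population.
#'
#' @inheritParams neutrophil_fate_fluxes
#' @return ITM release flux in tissue (molecules/mm3/h).
#' @export
necrosis_itm_release <- function(state, params) {
  params$values[["k_itm_release"]] * state[["nd_n"]]
}

#' ITM neutralisation by AP
#'
#' In blood, AP (endogenous and supplemented alike) binds ITMs 1:1 into
#' ITM-AP complexes that await Kupffer-cell clearance; binding consumes
#' both reactants. In tissue, AP dephosphorylates ITMs catalytically (AP
#' is not consumed).
#'
#' @inheritParams neutrophil_fate_fluxes
#' @return Named numeric: `binding_blood` (molecules/mm3/h, feeds
#'   `itm_ap_blood`) and `dephosphorylation_tissue` (molecules/mm3/h).
#' @export
itm_ap_neutralization <- function(state, params) {
  v <- params$values
  ap_b <- state[["ap_endo_blood"]] + state[["ap_supp_blood"]]
  ap_t <- state[["ap_endo_tissue"]] + state[["ap_supp_tissue"]]
  c(binding_blood = v[["k_bind"]] * state[["itm_blood"]] * ap_b,
    dephosphorylation_tissue = v[["k_deph"]] * ap_t * state[["itm_tissue"]])
}

# Smooth switches used by the liver compartment.
.liver_distress <- function(itm_blood, h) itm_blood^2 / (itm_blood^2 + h^2)

.liver_recovery_gate <- function(t, params, has_insult) {
  if (!has_insult) return(rep(1, length(t)))
  v <- params$values
  1 / (1 + exp(pmin(-v[["k_liver_recovery"]] *
                      (t - v[["t_liver_recovery"]]), 700)))
}

#' All mechanism fluxes at one instant
#'
#' Evaluates every per-mechanism flux of the model at `(t, state)`:
#' ITM kinetics, AP binding/dephosphorylation, liver flush/restock and de
#' novo supply, the induction term, bolus/infusion input, macrophage and
#' neutrophil population fluxes, cytokine production/decay, damage and the
#' delay chain. [rhs()] assembles the state derivatives from this list;
#' exposing it separately lets flux-level bookkeeping be audited
#' independently of the assembly.
#'
#' @param t Time (h), >= 0.
#' @param state Named state vector (see [state_names()]).
#' @param params A [model_parameters()] object.
#' @param protocol A [treatment_protocol()].
#' @param insult Optional secondary ITM source, an object from
#'   [generate_secondary_insult()] (or `NULL`).
#' @return Named list of fluxes (units per receiving pool per hour) plus
#'   auxiliaries `mu` (permeability), `mu0`, `sigma_distress`,
#'   `recovery_gate`.
#' @export
mechanism_fluxes <- function(t, state, params, protocol = placebo_protocol(),
                             insult = NULL) {
  # adaptive solvers probe slightly negative values near zero; fluxes are
  # evaluated on the non-negative part so such excursions decay back
  state <- pmax(state, 0)
  v <- params$values
  uc <- unit_constants()
  rho <- uc$rho_blood_tissue

  ch0 <- v[["ch0_pgml"]] * uc$cytokine_pg_ml_to_molec_mm3
  ach0 <- v[["ach0_pgml"]] * uc$cytokine_pg_ml_to_molec_mm3
  ap0 <- v[["ap_baseline_iul"]] * uc$ap_iu_per_l_to_molec_mm3
  mu <- endothelial_permeability(state[["ch"]], params)
  mu0 <- endothelial_permeability(ch0, params)

  has_insult <- v[["itm_insult"]] > 0 ||
    (!is.null(insult) && insult$amplitude > 0)
  sigma_d <- .liver_distress(state[["itm_blood"]], v[["h_liver_itm"]])
  gate <- .liver_recovery_gate(t, params, has_insult)

  neutral <- itm_ap_neutralization(state, params)
  fate <- neutrophil_fate_fluxes(state, params)
  ap_b_endo <- state[["ap_endo_blood"]]
  ap_b_supp <- state[["ap_supp_blood"]]
  ap_b_tot <- ap_b_endo + ap_b_supp
  bind_endo <- if (ap_b_tot > 0) {
    neutral[["binding_blood"]] * ap_b_endo / ap_b_tot
  } else 0
  bind_supp <- neutral[["binding_blood"]] - bind_endo

  recruit <- v[["k_diaped"]] * max(mu - mu0, 0) * state[["n_r"]]
  phag_nda <- v[["k_phag_nda"]] * state[["m_a"]] * state[["nd_a"]]
  inhib <- 1 / (1 + (state[["ach"]] / v[["h_ach_inh"]])^2)
  gdel <- state[["delay3"]] / (state[["delay3"]] + v[["h_ch_delay"]])
  kd <- 3 / v[["tau_delay"]]

  list(
    # blood ITM
    itm_secondary = if (is.null(insult)) 0 else insult_rate(insult, t),
    itm_deg_blood = v[["k_itm_deg_blood"]] * state[["itm_blood"]],
    itm_bt = mu * v[["k_itm_bt"]] * state[["itm_blood"]],
    bind_endo = bind_endo,
    bind_supp = bind_supp,
    kupffer = v[["k_kupffer"]] * state[["itm_ap_blood"]],
    # tissue ITM
    deph_tissue = neutral[["dephosphorylation_tissue"]],
    itm_deg_tissue = v[["k_itm_deg_tissue"]] * state[["itm_tissue"]],
    itm_phag_na = v[["k_phag_na"]] * state[["n_a"]] * state[["itm_tissue"]],
    itm_phag_ma = v[["k_phag_ma"]] * state[["m_a"]] * state[["itm_tissue"]],
    itm_release = necrosis_itm_release(state, params),
    # AP supply and turnover
    liver_release = v[["k_liver_flush"]] * sigma_d * state[["liver_store"]] *
      uc$iu_to_blood_conc,
    liver_flush_iu = v[["k_liver_flush"]] * sigma_d * state[["liver_store"]],
    liver_restock_iu = v[["k_liver_restock"]] * (1 - sigma_d) *
      (v[["liver_capacity_iu"]] - state[["liver_store"]]),
    denovo = ap0 * (v[["k_ap_deg_blood"]] + mu0 * v[["k_ap_bt"]]) * gate *
      (1 + v[["k_denovo_boost"]] *
         (if (ap0 > 0) max(0, 1 - state[["ap_endo_blood"]] / ap0) else 0)),
    induction = induction_rate(t, induction_parameters(params),
                               ap_b_supp + state[["ap_supp_tissue"]]),
    ap_endo_deg_blood = v[["k_ap_deg_blood"]] * ap_b_endo,
    ap_endo_bt = mu * v[["k_ap_bt"]] * ap_b_endo,
    ap_endo_deg_tissue = v[["k_ap_deg_tissue"]] * state[["ap_endo_tissue"]],
    bolus_in = v[["k_bolus"]] * state[["bolus_depot"]] * uc$iu_to_blood_conc,
    bolus_out_iu = v[["k_bolus"]] * state[["bolus_depot"]],
    infusion_in = infusion_rate_at(max(t, 0), protocol) * uc$iu_to_blood_conc,
    ap_supp_deg_blood = v[["k_aps_deg_blood"]] * ap_b_supp,
    ap_supp_bt = mu * v[["k_ap_bt"]] * ap_b_supp,
    ap_supp_deg_tissue = v[["k_ap_deg_tissue"]] * state[["ap_supp_tissue"]],
    # macrophages
    mr_source = v[["k_mr_death"]] * v[["m_r0"]],
    mr_death = v[["k_mr_death"]] * state[["m_r"]],
    mr_activation = v[["k_mr_act"]] * state[["itm_tissue"]] * state[["m_r"]],
    ma_death = v[["k_ma_death"]] * state[["m_a"]],
    # neutrophils
    nr_source = v[["k_nr_death"]] * v[["n_r0"]],
    nr_death = v[["k_nr_death"]] * state[["n_r"]],
    recruit = recruit,
    na_apoptosis = fate[["apoptosis"]],
    na_necrosis = fate[["necrosis"]],
    nda_phag = phag_nda,
    nda_deg = v[["k_nda_deg"]] * state[["nd_a"]],
    ndn_phag = v[["k_phag_ndn"]] * state[["m_a"]] * state[["nd_n"]],
    ndn_deg = v[["k_ndn_deg"]] * state[["nd_n"]],
    # cytokines (blood-appearance rates from tissue cells)
    ch_source = v[["k_ch_deg"]] * ch0,
    ch_prod = inhib * gdel *
      (v[["k_ch_ma"]] * state[["m_a"]] + v[["k_ch_ndn"]] * state[["nd_n"]]),
    ch_deg = v[["k_ch_deg"]] * state[["ch"]],
    ach_source = v[["k_ach_deg"]] * ach0,
    ach_prod = v[["k_ach_ma"]] * state[["m_a"]] +
      v[["k_ach_phag"]] * phag_nda,
    ach_deg = v[["k_ach_deg"]] * state[["ach"]],
    # damage mediator
    d_prod = v[["k_d_ndn"]] * state[["nd_n"]] +
      v[["k_d_itm"]] * state[["itm_tissue"]],
    d_deg = v[["k_d_deg"]] * state[["d"]],
    # delay chain
    delay1_flux = kd * (state[["itm_tissue"]] - state[["delay1"]]),
    delay2_flux = kd * (state[["delay1"]] - state[["delay2"]]),
    delay3_flux = kd * (state[["delay2"]] - state[["delay3"]]),
    # auxiliaries
    mu = mu, mu0 = mu0, sigma_distress = sigma_d, recovery_gate = gate,
    rho = rho
  )
}

#' Right-hand side of the blood-tissue-liver inflammation model
#'
#' Assembles the time derivative of every state variable from the
#' mechanism fluxes: ITM transport and neutralisation, liver store flush,
#' restock and de novo AP supply (with the supplementation-driven
#' induction term), bolus/infusion delivery, macrophage activation,
#' permeability-driven neutrophil recruitment and dual-pathway death,
#' cytokine production and decay, tissue damage, and the Erlang delay
#' chain. Transport between compartments is volume-corrected with the
#' blood/tissue volume ratio.
#'
#' @inheritParams mechanism_fluxes
#' @return Named numeric vector `d(state)/dt` in state order.
#' @export
rhs <- function(t, state, params, protocol = placebo_protocol(),
                insult = NULL) {
  if (any(!is.finite(state))) {
    bad <- state_names()[!is.finite(state)]
    stop("non-finite state component(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  f <- mechanism_fluxes(t, state, params, protocol, insult)
  rho <- f$rho
  v <- params$values
  d <- c(
    itm_blood = f$itm_secondary - f$itm_deg_blood - f$itm_bt -
      f$bind_endo - f$bind_supp,
    itm_tissue = rho * f$itm_bt + f$itm_release - f$deph_tissue -
      f$itm_deg_tissue - f$itm_phag_na - f$itm_phag_ma,
    ap_endo_blood = f$liver_release + f$denovo + f$induction -
      f$ap_endo_deg_blood - f$ap_endo_bt - f$bind_endo,
    ap_endo_tissue = rho * f$ap_endo_bt - f$ap_endo_deg_tissue,
    ap_supp_blood = f$bolus_in + f$infusion_in - f$ap_supp_deg_blood -
      f$ap_supp_bt - f$bind_supp,
    ap_supp_tissue = rho * f$ap_supp_bt - f$ap_supp_deg_tissue,
    itm_ap_blood = f$bind_endo + f$bind_supp - f$kupffer,
    m_r = f$mr_source - f$mr_death - f$mr_activation,
    m_a = f$mr_activation - f$ma_death,
    n_r = f$nr_source - f$nr_death - f$recruit,
    n_a = rho * f$recruit - f$na_apoptosis - f$na_necrosis,
    nd_a = f$na_apoptosis - f$nda_phag - f$nda_deg,
    nd_n = f$na_necrosis - f$ndn_phag - f$ndn_deg,
    ch = f$ch_source + f$ch_prod - f$ch_deg,
    ach = f$ach_source + f$ach_prod - f$ach_deg,
    d = f$d_prod - f$d_deg,
    liver_store = f$liver_restock_iu - f$liver_flush_iu,
    bolus_depot = -f$bolus_out_iu,
    delay1 = f$delay1_flux,
    delay2 = f$delay2_flux,
    delay3 = f$delay3_flux
  )
  stats::setNames(as.numeric(d), state_names())
}

# Fast inlined right-hand side used by the integrator. Same formulas as
# rhs()/mechanism_fluxes(), with constants and parameter lookups hoisted
# out of the per-step call; tests pin it bit-identical to rhs().
.rhs_fast <- function(params, protocol, insult = NULL) {
  v <- params$values
  uc <- unit_constants()
  rho <- uc$rho_blood_tissue
  ch0 <- v[["ch0_pgml"]] * uc$cytokine_pg_ml_to_molec_mm3
  ach0 <- v[["ach0_pgml"]] * uc$cytokine_pg_ml_to_molec_mm3
  ap0 <- v[["ap_baseline_iul"]] * uc$ap_iu_per_l_to_molec_mm3
  perm_max <- v[["perm_max"]]; h_perm <- v[["h_perm"]]
  mu0 <- 1 + perm_max / (1 + (h_perm / ch0)^2)
  iu2c <- uc$iu_to_blood_conc
  has_insult <- v[["itm_insult"]] > 0 ||
    (!is.null(insult) && insult$amplitude > 0)
  enabled <- isTRUE(params$induction_enabled)
  inf_rate <- if (protocol$infusion_total_iu > 0) {
    protocol$infusion_total_iu / protocol$infusion_duration_h *
      protocol$scale
  } else 0
  inf_dur <- protocol$infusion_duration_h
  ins_amp <- if (is.null(insult)) 0 else insult$amplitude
  ins_c <- if (is.null(insult)) 0 else insult$center_h
  ins_w <- if (is.null(insult)) 1 else insult$width_h
  k_itm_deg_b <- v[["k_itm_deg_blood"]]; k_itm_bt <- v[["k_itm_bt"]]
  k_itm_deg_t <- v[["k_itm_deg_tissue"]]; k_bind <- v[["k_bind"]]
  k_deph <- v[["k_deph"]]; k_phag_na <- v[["k_phag_na"]]
  k_phag_ma <- v[["k_phag_ma"]]; k_itm_rel <- v[["k_itm_release"]]
  k_kupffer <- v[["k_kupffer"]]; k_ap_deg_b <- v[["k_ap_deg_blood"]]
  k_aps_deg_b <- v[["k_aps_deg_blood"]]; k_ap_bt <- v[["k_ap_bt"]]
  k_ap_deg_t <- v[["k_ap_deg_tissue"]]
  liver_cap <- v[["liver_capacity_iu"]]; k_flush <- v[["k_liver_flush"]]
  h_liver2 <- v[["h_liver_itm"]]^2; k_restock <- v[["k_liver_restock"]]
  t_rec <- v[["t_liver_recovery"]]; k_rec <- v[["k_liver_recovery"]]
  boost <- v[["k_denovo_boost"]]
  rp <- v[["r_induce_peak"]]; ri <- v[["r_induce"]]
  t1 <- v[["t_ap_delay"]]
  m_r0 <- v[["m_r0"]]; k_mr_act <- v[["k_mr_act"]]
  k_mr_death <- v[["k_mr_death"]]; k_ma_death <- v[["k_ma_death"]]
  n_r0 <- v[["n_r0"]]; k_nr_death <- v[["k_nr_death"]]
  k_diaped <- v[["k_diaped"]]; k_apop <- v[["k_na_apop"]]
  k_nec_max <- v[["k_na_nec_max"]]; k_nec_min <- v[["k_na_nec_min"]]
  h_nec <- v[["h_nec"]]; k_phag_nda <- v[["k_phag_nda"]]
  k_phag_ndn <- v[["k_phag_ndn"]]; k_nda_deg <- v[["k_nda_deg"]]
  k_ndn_deg <- v[["k_ndn_deg"]]; k_ch_ma <- v[["k_ch_ma"]]
  k_ch_ndn <- v[["k_ch_ndn"]]; h_ch_delay <- v[["h_ch_delay"]]
  h_ach_inh <- v[["h_ach_inh"]]; k_ch_deg <- v[["k_ch_deg"]]
  k_ach_deg <- v[["k_ach_deg"]]; k_ach_ma <- v[["k_ach_ma"]]
  k_ach_phag <- v[["k_ach_phag"]]; k_d_ndn <- v[["k_d_ndn"]]
  k_d_itm <- v[["k_d_itm"]]; k_d_deg <- v[["k_d_deg"]]
  kd <- 3 / v[["tau_delay"]]; k_bolus <- v[["k_bolus"]]
  s_mr <- k_mr_death * m_r0
  s_nr <- k_nr_death * n_r0
  s_ch <- k_ch_deg * ch0
  s_ach <- k_ach_deg * ach0
  denovo0 <- ap0 * (k_ap_deg_b + mu0 * k_ap_bt)

  function(t, y) {
    y <- pmax(y, 0)
    itm_b <- y[1]; itm_t <- y[2]; ap_eb <- y[3]; ap_et <- y[4]
    ap_sb <- y[5]; ap_st <- y[6]; cplx <- y[7]; m_r <- y[8]; m_a <- y[9]
    n_r <- y[10]; n_a <- y[11]; nd_a <- y[12]; nd_n <- y[13]
    ch <- y[14]; ach <- y[15]; dmg <- y[16]; liver <- y[17]
    depot <- y[18]; x1 <- y[19]; x2 <- y[20]; x3 <- y[21]

    mu <- 1 + perm_max / (1 + (h_perm / ch)^2)
    sigma_d <- itm_b^2 / (itm_b^2 + h_liver2)
    gate <- if (has_insult) 1 / (1 + exp(min(-k_rec * (t - t_rec), 700)))
            else 1
    binding <- k_bind * itm_b * (ap_eb + ap_sb)
    ap_b_tot <- ap_eb + ap_sb
    bind_endo <- if (ap_b_tot > 0) binding * ap_eb / ap_b_tot else 0
    bind_supp <- binding - bind_endo
    deph <- k_deph * (ap_et + ap_st) * itm_t
    drive <- 0.5 * (itm_t + x3)
    sigma_nec <- drive / (drive + h_nec)
    f_apop <- k_apop * n_a
    f_nec <- (k_nec_min + k_nec_max * sigma_nec) * n_a
    recruit <- k_diaped * max(mu - mu0, 0) * n_r
    phag_nda <- k_phag_nda * m_a * nd_a
    inhib <- 1 / (1 + (ach / h_ach_inh)^2)
    gdel <- x3 / (x3 + h_ch_delay)
    f_sec <- if (ins_amp > 0) {
      ins_amp * exp(-(t - ins_c)^2 / (2 * ins_w^2))
    } else 0
    f_itm_bt <- mu * k_itm_bt * itm_b
    f_ap_endo_bt <- mu * k_ap_bt * ap_eb
    f_ap_supp_bt <- mu * k_ap_bt * ap_sb
    flush <- k_flush * sigma_d * liver
    denovo <- denovo0 * gate *
      (1 + boost * (if (ap0 > 0) max(0, 1 - ap_eb / ap0) else 0))
    induct <- if (enabled) {
      rp / (1 + exp(min(ri * (t - t1), 700))) * (ap_sb + ap_st)
    } else 0
    f_inf <- if (inf_rate > 0 && t < inf_dur) inf_rate * iu2c else 0
    mr_act <- k_mr_act * itm_t * m_r

    c(f_sec - k_itm_deg_b * itm_b - f_itm_bt - bind_endo - bind_supp,
      rho * f_itm_bt + k_itm_rel * nd_n - deph - k_itm_deg_t * itm_t -
        k_phag_na * n_a * itm_t - k_phag_ma * m_a * itm_t,
      flush * iu2c + denovo + induct - k_ap_deg_b * ap_eb -
        f_ap_endo_bt - bind_endo,
      rho * f_ap_endo_bt - k_ap_deg_t * ap_et,
      k_bolus * depot * iu2c + f_inf - k_aps_deg_b * ap_sb -
        f_ap_supp_bt - bind_supp,
      rho * f_ap_supp_bt - k_ap_deg_t * ap_st,
      bind_endo + bind_supp - k_kupffer * cplx,
      s_mr - k_mr_death * m_r - mr_act,
      mr_act - k_ma_death * m_a,
      s_nr - k_nr_death * n_r - recruit,
      rho * recruit - f_apop - f_nec,
      f_apop - phag_nda - k_nda_deg * nd_a,
      f_nec - k_phag_ndn * m_a * nd_n - k_ndn_deg * nd_n,
      s_ch + inhib * gdel * (k_ch_ma * m_a + k_ch_ndn * nd_n) -
        k_ch_deg * ch,
      s_ach + k_ach_ma * m_a + k_ach_phag * phag_nda - k_ach_deg * ach,
      k_d_ndn * nd_n + k_d_itm * itm_t - k_d_deg * dmg,
      k_restock * (1 - sigma_d) * (liver_cap - liver) - flush,
      -k_bolus * depot,
      kd * (itm_t - x1),
      kd * (x1 - x2),
      kd * (x2 - x3))
  }
}
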