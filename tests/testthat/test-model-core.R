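test_that("induction term follows the reverse sigmoid in time", {
  ip <- induction_parameters(nominal_params())
  S <- 3.7e8
  # exact half-peak at the sigmoid centre
  expect_equal(induction_rate(ip$t_ap_delay, ip, S),
               ip$r_induce_peak * S / 2, tolerance = 1e-12)
  # multiplicative zero in supplemented AP
  expect_equal(induction_rate(c(0, 1, 10), ip, 0), c(0, 0, 0))
  # deep tail: coefficient below 1e-20 of peak
  t_far <- ip$t_ap_delay + 50 / ip$r_induce
  expect_lt(induction_rate(t_far, ip, S), 1e-20 * ip$r_induce_peak * S)
  # disabled flag forces exact zero
  ip_off <- ip
  ip_off$enabled <- FALSE
  expect_identical(induction_rate(5, ip_off, S), 0)
  expect_error(induction_rate(1, ip, -1), ">= 0")
})

test_that("endothelial permeability is monotone, baselined and saturating", {
  p <- nominal_params()
  expect_equal(endothelial_permeability(0, p), 1)
  ch <- sort(stats::runif(50, 0, 1e8))
  mu <- endothelial_permeability(ch, p)
  expect_true(all(diff(mu) >= 0))
  # analytic saturation limit of the Hill form
  expect_equal(endothelial_permeability(1e300, p),
               1 + p$values[["perm_max"]])
  expect_error(endothelial_permeability(-1, p), ">= 0")
})

test_that("neutrophil fates split the outflux and favour necrosis under ITM", {
  p <- nominal_params()
  s <- homeostatic_state(p)
  # no activated neutrophils -> both fluxes vanish
  f0 <- neutrophil_fate_fluxes(s, p)
  expect_equal(unname(f0), c(0, 0))
  s[["n_a"]] <- 500
  low <- s
  high <- s
  low[["itm_tissue"]] <- 1e9
  high[["itm_tissue"]] <- 1e11
  share <- function(f) f[["necrosis"]] / (f[["necrosis"]] + f[["apoptosis"]])
  expect_gt(share(neutrophil_fate_fluxes(high, p)),
            share(neutrophil_fate_fluxes(low, p)))
  # cleared inflammation: apoptosis dominates, necrosis at its floor
  clear <- s
  clear[["itm_tissue"]] <- 0
  fc <- neutrophil_fate_fluxes(clear, p)
  expect_equal(fc[["necrosis"]], p$values[["k_na_nec_min"]] * 500)
  expect_gt(fc[["apoptosis"]], fc[["necrosis"]])
  # both fluxes always non-negative
  for (st in random_states(20)) {
    f <- neutrophil_fate_fluxes(st, p)
    expect_true(all(f >= 0))
  }
})

test_that("necrotic neutrophils are a linear ITM source in tissue", {
  p <- nominal_params()
  s <- homeostatic_state(p)
  expect_equal(necrosis_itm_release(s, p), 0)
  s[["nd_n"]] <- 120
  r1 <- necrosis_itm_release(s, p)
  expect_gt(r1, 0)
  s[["nd_n"]] <- 240
  expect_equal(necrosis_itm_release(s, p), 2 * r1)
})

test_that("ITM-AP neutralisation respects zeros and 1:1 stoichiometry", {
  p <- nominal_params()
  s <- random_states(1)[[1]]
  s[["itm_blood"]] <- 0
  expect_equal(unname(itm_ap_neutralization(s, p)[["binding_blood"]]), 0)
  s2 <- random_states(2)[[2]]
  s2[c("ap_endo_blood", "ap_supp_blood",
       "ap_endo_tissue", "ap_supp_tissue")] <- 0
  expect_equal(unname(itm_ap_neutralization(s2, p)), c(0, 0))
  # 1:1 bookkeeping in the assembled derivatives: complex gain equals
  # ITM binding loss equals AP binding loss
  s3 <- random_states(3)[[3]]
  f <- mechanism_fluxes(0.7, s3, p, appired2_protocol())
  binding <- itm_ap_neutralization(pmax(s3, 0), p)[["binding_blood"]]
  expect_equal(f$bind_endo + f$bind_supp, binding, tolerance = 1e-12)
  d <- rhs(0.7, s3, p, appired2_protocol())
  # remove non-binding terms to isolate the stoichiometry
  expect_equal(d[["itm_ap_blood"]] + f$kupffer, binding, tolerance = 1e-9)
})

test_that("the homeostatic state is an exact fixed point of the rhs", {
  p0 <- model_parameters(itm_insult = 0)
  s <- homeostatic_state(p0)
  d <- rhs(0, s, p0, placebo_protocol())
  expect_lt(max(abs(d) / pmax(abs(s), 1)), 1e-12)
  # no tissue ITM, no blood ITM -> no macrophage activation flux
  f <- mechanism_fluxes(0, s, p0, placebo_protocol())
  expect_equal(f$mr_activation, 0)
})

test_that("rhs equals an independent stoichiometry-matrix assembly of the
           mechanism fluxes at 100 random states", {
  p <- nominal_params()
  proto <- appired2_protocol()
  ins <- generate_secondary_insult(synth_config())
  rho <- unit_constants()$rho_blood_tissue
  # independent bookkeeping: receiving-state x flux incidence table
  ledger <- list(
    itm_blood = c(itm_secondary = 1, itm_deg_blood = -1, itm_bt = -1,
                  bind_endo = -1, bind_supp = -1),
    itm_tissue = c(itm_bt = rho, itm_release = 1, deph_tissue = -1,
                   itm_deg_tissue = -1, itm_phag_na = -1, itm_phag_ma = -1),
    ap_endo_blood = c(liver_release = 1, denovo = 1, induction = 1,
                      ap_endo_deg_blood = -1, ap_endo_bt = -1,
                      bind_endo = -1),
    ap_endo_tissue = c(ap_endo_bt = rho, ap_endo_deg_tissue = -1),
    ap_supp_blood = c(bolus_in = 1, infusion_in = 1,
                      ap_supp_deg_blood = -1, ap_supp_bt = -1,
                      bind_supp = -1),
    ap_supp_tissue = c(ap_supp_bt = rho, ap_supp_deg_tissue = -1),
    itm_ap_blood = c(bind_endo = 1, bind_supp = 1, kupffer = -1),
    m_r = c(mr_source = 1, mr_death = -1, mr_activation = -1),
    m_a = c(mr_activation = 1, ma_death = -1),
    n_r = c(nr_source = 1, nr_death = -1, recruit = -1),
    n_a = c(recruit = rho, na_apoptosis = -1, na_necrosis = -1),
    nd_a = c(na_apoptosis = 1, nda_phag = -1, nda_deg = -1),
    nd_n = c(na_necrosis = 1, ndn_phag = -1, ndn_deg = -1),
    ch = c(ch_source = 1, ch_prod = 1, ch_deg = -1),
    ach = c(ach_source = 1, ach_prod = 1, ach_deg = -1),
    d = c(d_prod = 1, d_deg = -1),
    liver_store = c(liver_restock_iu = 1, liver_flush_iu = -1),
    bolus_depot = c(bolus_out_iu = -1),
    delay1 = c(delay1_flux = 1),
    delay2 = c(delay2_flux = 1),
    delay3 = c(delay3_flux = 1))
  set.seed(99)
  times <- stats::runif(100, 0, 36)
  states <- random_states(100)
  for (i in seq_len(100)) {
    f <- mechanism_fluxes(times[i], states[[i]], p, proto, ins)
    expected <- vapply(state_names(), function(vn) {
      w <- ledger[[vn]]
      sum(w * unlist(f[names(w)]))
    }, numeric(1))
    got <- rhs(times[i], states[[i]], p, proto, ins)
    denom <- pmax(abs(expected), abs(got), 1e-300)
    mism <- abs(got - expected) / denom
    mism[expected == 0 & got == 0] <- 0
    expect_lt(max(mism), 1e-12)
  }
})

test_that("rhs rejects non-finite states, naming the component", {
  p <- nominal_params()
  s <- homeostatic_state(p)
  s[["ch"]] <- NaN
  expect_error(rhs(0, s, p), "ch")
})

test_that("parameter sets validate, update and serialise losslessly", {
  p <- model_parameters(free = c("r_induce_peak", "t_ap_delay"))
  expect_error(model_parameters(k_bind = -1), "non-negative")
  expect_error(model_parameters(no_such = 1), "unknown")
  expect_error(set_parameter_values(p, c(nope = 1)), "unknown")
  expect_true(all(p$lower <= p$values & p$values <= p$upper))

  p2 <- set_parameter_values(p, c(r_induce = 3.3))
  expect_equal(p2$values[["r_induce"]], 3.3)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_parameters(p2, path)
  p3 <- read_parameters(path)
  expect_identical(p3$values, p2$values)
  expect_identical(p3$lower, p2$lower)
  expect_identical(p3$upper, p2$upper)
  expect_identical(p3$free, p2$free)
  expect_identical(p3$induction_enabled, p2$induction_enabled)
})

test_that("all-zero initial state yields the zero trajectory", {
  p <- model_parameters(itm_insult = 0, ap_baseline_iul = 0,
                        ch0_pgml = 0, ach0_pgml = 0, m_r0 = 0, n_r0 = 0,
                        liver_capacity_iu = 0)
  s0 <- stats::setNames(numeric(21), state_names())
  tr <- integrate_model(p, placebo_protocol(), horizon = 4, state0 = s0)
  expect_equal(max(abs(tr$states)), 0)
})
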