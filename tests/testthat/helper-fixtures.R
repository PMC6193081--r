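# Shared fixtures, memoised so expensive ODE solves run once per session.
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- force(expr)
  }
  .fixture_cache[[key]]
}

nominal_params <- function() memo("params", model_parameters())

placebo_run <- function() {
  memo("placebo_run", integrate_model(nominal_params(), placebo_protocol()))
}

biap_run <- function() {
  memo("biap_run", integrate_model(nominal_params(), appired2_protocol()))
}

homeostatic_run <- function() {
  memo("homeo_run",
       integrate_model(model_parameters(itm_insult = 0), placebo_protocol()))
}

noiseless_series <- function() {
  memo("noiseless_series",
       generate_clinical_series(synth_config(noise_fraction = 0)))
}

noisy_series <- function() {
  memo("noisy_series", generate_clinical_series(synth_config(seed = 11)))
}

# Random valid states spanning the dynamic range seen along trajectories,
# used by flux-ledger and monotonicity property tests.
random_states <- function(n, seed = 421) {
  set.seed(seed)
  base <- homeostatic_state(nominal_params())
  base[c("itm_blood", "itm_tissue")] <- 1e10
  base[c("ap_supp_blood", "itm_ap_blood")] <- 1e8
  base[["ap_supp_tissue"]] <- 1e7
  base[c("m_a", "n_a", "nd_a", "nd_n")] <- c(300, 400, 200, 100)
  base[["d"]] <- 1e3
  base[["bolus_depot"]] <- 100
  base[c("delay1", "delay2", "delay3")] <- c(1e10, 5e9, 1e9)
  lapply(seq_len(n), function(i) {
    s <- base * stats::rlnorm(length(base), 0, 1)
    s[sample.int(length(s), 2)] <- 0
    stats::setNames(pmax(s, 0), state_names())
  })
}
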