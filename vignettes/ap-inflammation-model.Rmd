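---
title: "A blood-tissue-liver model of alkaline phosphatase in systemic inflammation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A blood-tissue-liver model of alkaline phosphatase in systemic inflammation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Open-heart surgery under cardiopulmonary bypass floods the circulation with
inflammation-triggering moieties (ITMs) — lipopolysaccharide, extracellular
ATP/ADP and related phosphorylated signals released by damaged blood cells
and hypo-perfused gut. The innate immune response they trigger is systemic:
macrophage activation, cytokine release, endothelial opening, neutrophil
influx, and a split between anti-inflammatory (apoptotic) and
pro-inflammatory (necrotic) neutrophil death. Alkaline phosphatase (AP)
counters the insult by dephosphorylating ITMs — in plasma by forming
ITM-AP complexes that Kupffer cells clear, in tissue by catalytic
detoxification. Clinically, supplementing bovine intestinal AP (bIAP,
bolus plus infusion) around surgery is associated with a surge of
endogenous liver-type tissue-nonspecific AP (TNAP) in plasma, suggesting
that supplemented AP *induces* extra endogenous AP release.

`apsirs` implements a deterministic compartmental ODE model of this system
and everything needed to interrogate it: simulation of treatment
protocols, calibration against sparse cohort-median time series,
cross-branch validation, an induction-ablation comparison, secondary
insult and dose-scaling predictions, variance-based global sensitivity
analysis, and a seeded pseudo-clinical data generator. Patient-level trial
data are not publicly deposited, so the generator is a first-class part of
the package: every analysis runs end-to-end on synthetic cohorts with a
known ground truth.

## Model structure

Three compartments: **blood** (free ITM, endogenous AP, supplemented AP,
ITM-AP complexes, resting neutrophils, pro- and anti-inflammatory
cytokines), **tissue** (ITM, both AP pools, resting/activated macrophages,
activated/apoptotic/necrotic neutrophils, a damage tracker), and the
**liver** (a releasable AP store of ~5,300 IU). Twenty-one state
variables in total, including a bolus delivery depot and a three-stage
delay chain. Internal units are hours, molecules/mm³ for molecules and
cells/mm³ for cells; IU/L (AP activity) and pg/mL (cytokines) appear only
at I/O boundaries, converted with factors derived from a 160 kDa enzyme at
1,000 IU/mg, a 20 kDa representative cytokine mass, and a 5 L blood /
15 L interstitium volume split (`unit_constants()`).

The mechanisms, in the order they fire after the surgical insult
(an initial blood ITM load `itm_insult`):

* **ITM kinetics.** First-order degradation in both compartments;
  blood-to-tissue transport scaled by endothelial permeability; in blood,
  mass-action binding to AP (1:1, consuming both, complexes cleared by
  Kupffer cells at `k_kupffer`); in tissue, catalytic dephosphorylation
  at rate `k_deph * AP_tissue` plus phagocytic removal by activated
  neutrophils and macrophages; necrotic neutrophils re-release ITMs
  (`k_itm_release` per cell) — the positive feedback of unresolved
  inflammation.
* **Endothelial permeability.** A saturating Hill function (n = 2) of the
  pro-inflammatory cytokine, equal to 1 at zero cytokine (fenestral
  baseline) and saturating at `1 + perm_max`. Neutrophil recruitment is
  proportional to the permeability *excess* over its homeostatic value, so
  the resting state recruits nobody.
* **Macrophages and neutrophils.** Mass-action activation of resting
  macrophages by tissue ITM (fast — the resting pool empties within the
  first hour of a massive insult); recruitment (diapedesis) of resting
  blood neutrophils into tissue; dual-pathway death of activated
  neutrophils, with the necrotic fraction a saturating function of the
  inflammation drive. The drive blends instantaneous tissue ITM with its
  low-pass-filtered (delayed) signal; the filter is a linear chain of
  three first-order stages with mean lag `tau_delay` (6 h), an Erlang
  delay that keeps the system a pure ODE. Activated macrophages clear
  apoptotic neutrophils (anti-inflammatory) and, more slowly, necrotic
  debris.
* **Cytokines.** Produced (with the delayed gate and an anti-inflammatory
  inhibition factor) by activated macrophages and necrotic neutrophils;
  the anti-inflammatory cytokine is driven mainly by efferocytosis — the
  phagocytic clearance of apoptotic neutrophils — which is what gives AP
  supplementation its anti-inflammatory signature. Both have homeostatic
  source/decay turnover so the resting state is an exact fixed point.
* **Liver.** A distress switch (Hill in blood ITM) flushes the stored
  pool at `k_liver_flush` (25/h, effectively complete within ~10 min);
  restocking is gated off while distress persists, so the flush releases
  the stored ~5,300 IU once. De novo supply is gated by a smooth
  sigmoid in time with midpoint `t_liver_recovery` (2 h) — active only in
  insult scenarios, so homeostasis is untouched — and up-regulated in
  proportion to the blood AP deficit (`k_denovo_boost`), which produces
  the observed trough-then-recovery of plasma AP with the trough near
  2 h.
* **Induction.** The supplementation-driven induction of endogenous TNAP
  enters the endogenous-AP supply as
  `r_induce_peak / (1 + exp(r_induce * (t - t_ap_delay))) * (APs_tissue + APs_blood)`:
  a reverse sigmoid in time, centred at `t_ap_delay = 1` h, proportional
  to the total supplemented AP. It is identically zero in the placebo arm
  (no supplemented AP) and under the ablation switch
  (`induction_enabled = FALSE`) — placebo trajectories are bit-identical
  either way, which the tests assert.
* **Damage `d`.** A passive accumulator driven by necrotic neutrophils
  and tissue ITM with slow first-order decay. It is a diagnostic readout
  of cumulative injury and deliberately has no feedback into the loop:
  the data available to constrain such a feedback (AP, IL-6, IL-10
  medians) contain no signal to identify it, and an unconstrained
  feedback would destabilise calibration.

Dosing: the bolus enters through a depot emptying at 100/h (a ~3-min
delivery, smooth for the stiff solver, indistinguishable from an impulse
at the 15-min observation scale); the infusion is a piecewise-constant
source with a solver restart at switch-off. Supplemented AP follows the
same transport and tissue kinetics as endogenous AP but has its own blood
clearance (`k_aps_deg_blood`, 10/h): bovine AP's plasma half-life is
minutes, which is exactly why the bolus's own contribution to plasma AP
vanishes within ~20 minutes while the endogenous surge it induces persists
for hours. A single shared clearance rate cannot reproduce both
observations at once.

## Homeostasis by construction

All source terms are derived from the baselines (`ap_baseline_iul`,
`ch0_pgml`, `ach0_pgml`, `m_r0`, `n_r0`) so that the resting state is an
exact algebraic fixed point: with zero ITM and no treatment, every
derivative is zero to machine precision, and a 36 h run stays within
1e-6 of its start. This is load-bearing for calibration — any drift would
alias into the fitted kinetics.

## Parameters

The full table (nominal value, box bounds, free/fixed flag) lives in
`model_parameters()`; `write_parameters()`/`read_parameters()` serialise
it losslessly as a flat key-value text file. Nominal values were chosen
once to reproduce the clinical anchors on the simulated cohort —
baseline AP ~50 IU/L, an AP trough near 2 h, bolus transience under
20 min, IL-6 peaking at a few hundred pg/mL within the first day, IL-10
tens of pg/mL, neutrophil counts of a few thousand cells/mm³ — and are
not re-derived from any patient-level source. Bounds are generally one
order of magnitude around the nominal value and double as the default
calibration box and the sensitivity-analysis ranges.

The parameters that matter most (units; default):

| parameter | meaning | default |
|---|---|---|
| `itm_insult` | surgical ITM load in blood at t = 0 (molecules/mm³) | 5e11 |
| `k_bind` | blood ITM + AP complexation (mm³/molecule/h) | 1e-11 |
| `k_aps_deg_blood` | supplemented-AP blood clearance (1/h) | 10 |
| `liver_capacity_iu` | stored hepatic AP pool (IU) | 5300 |
| `k_liver_flush` | distress-triggered release (1/h) | 25 |
| `t_liver_recovery` | de novo recovery midpoint (h) | 2 |
| `k_denovo_boost` | deficit-driven supply up-regulation (–) | 4 |
| `r_induce_peak` | induction peak coefficient (1/h) | 1.8 |
| `r_induce` | induction sigmoid steepness (1/h) | 0.35 |
| `t_ap_delay` | induction sigmoid centre (h) | 1 |

The induction steepness deserves a note: the clinical anchor fixes only
the sigmoid *centre* (1 h). The default slope is gentle, which keeps the
induction coefficient materially above zero through the infusion window —
a steep sigmoid would confine induction to the first hour, when
circulating ITMs consume AP fastest, and the induced surge would be almost
invisible in plasma. The gentle default makes the induced TNAP
contribution an identifiable feature of the supplemented arm, which is
what the ablation study tests.

## Numerical choices

`integrate_model()` uses `deSolve::lsoda` with rtol 1e-6 / atol 1e-9,
5-min dense output over a 36 h horizon, and a restart at the infusion
switch. Solver probing can push near-zero states a hair negative; fluxes
are evaluated on the clamped non-negative state (so excursions decay
back), the emitted trajectory is clamped at zero, and substantial
negativity (beyond ~1e3 × atol) aborts with an error rather than being
masked. Tolerance halving changes no component by more than 1e-4 of its
range (asserted in the tests), and identical inputs give bit-identical
trajectories. Summaries (peaks, AUCs) are grid-independent to 1% for all
slow variables; the deliberate sub-grid onset transients — the 3-min
bolus depot, the supplemented/endogenous blood-AP spikes it feeds, and
the 25/h liver flush — need the 1-min grid if their own peaks are the
quantity of interest.

Calibration minimises MAE-weighted least squares,
`sum(((model - median) / mae)^2)` in clinical units — the uncertainty the
cohort medians actually come with. The optimizer is a seeded
Latin-hypercube screen of the bounds followed by Nelder-Mead refinement on
a logit-transformed scale (bounds respected without penalties); integration
failures yield `+Inf` loss with a warning so the search can continue.
Degenerate boxes (bounds collapsed to a point) short-circuit to that point.
The default free set is the induction triple; all cell-kinetic rates stay
fixed at their nominals, since three observed series cannot identify the
full table.

## The synthetic cohort generator

`generate_clinical_series()` emulates what the clinical analysis consumes:
per branch (placebo and bolus + 8 h infusion totalling 9,000 IU), the
three observables AP (IU/L), IL-6 and IL-10 (pg/mL) at the sparse schedule
0, 0.25, 0.5, 1, 2, 4, 8, 12, 24, 36 h; at each point a cohort of 25
patients (the trial branch sizes were 25/27) is drawn with multiplicative
log-normal noise (sd fraction 0.25, a typical inter-patient spread for
these assays), and the reported median and median absolute deviation are
the cohort statistics, floored at assay detection levels (1 IU/L,
0.5 pg/mL). What it deliberately does not emulate: patient covariates,
dropout, assay drift, correlated errors across observables, or any
systematic model misspecification — so passing recovery and ablation tests
demonstrates internal identifiability under the stated noise model, not
robustness to structural error in real cohorts.

The secondary-insult scenario (complications after surgery) is a Gaussian
ITM source in blood, centred at 6 h with 1 h width, with total load equal
to the primary insult by default (`insult_multiple = 1`); the clinical
anchor for its magnitude is qualitative, so the multiple is configurable
and reports flag it.

## The in-silico studies

* `run_branch_comparison()` — placebo vs supplemented arm under identical
  kinetics: asserts more necrotic neutrophils and pro-inflammatory
  cytokine in placebo, more apoptotic neutrophils in the supplemented
  arm. Orderings are asserted on peak values and AUCs; pointwise curve
  dominance is not asserted because the curves may cross transiently near
  onset.
* `run_ablation_study()` — the structural test of induction: fit the
  induction model on the supplemented branch and predict placebo; fit the
  ablated model (no induction) on placebo and predict the supplemented
  branch. On data generated *with* induction, the ablated model's AP
  residual on the supplemented branch exceeds the full model's several
  times over; on data generated without induction the two are comparable.
* `run_excess_itm_experiment()` — both arms under the secondary insult;
  the four protective orderings (apoptotic up, necrotic down, IL-6 down,
  IL-10 up in the supplemented arm).
* `run_dose_scaling()` — the protocol at 1×/2×/3×: monotone protection in
  all six tracked quantities.
* `sensitivity_analysis()` — Saltelli cross-sampling with first-order
  (Saltelli 2010) and total (Jansen) Sobol estimators, bootstrap CIs, on
  four outputs: peak IL-6, tissue-ITM AUC, peak necrotic neutrophils, and
  the blood-AP trough. The estimators are validated in the tests against
  the closed-form indices of a linear toy model.

## Problem sizes used in the shipped tests

The test suite runs the full pipeline at sizes a laptop handles in
minutes: single-seed noiseless recovery of the induction triple with a
300-point global screen and 300 local steps; ablation studies with a
100-point screen; Sobol validation at 1,000-4,000 base samples on the
toy model and 64 on the ODE model. The same machinery scales to larger
screens by passing `n_global`/`n_samples`.

## Known limitations

The model is a cohort-median description — no patient-level variability
in kinetics, no covariates, no clustering of responders. The D equation is
a passive tracker. Transport coefficients absorb the geometry of the
endothelial barrier rather than resolving it; spatial effects beyond the
three compartments are out of scope by design. The induced-TNAP mechanism
is one plausible functional form (reverse sigmoid × supplemented AP), and
the ablation study shows the *data need it*, not that it is unique.
Conversion constants are derived from representative molecular masses;
absolute internal concentrations inherit that convention.
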