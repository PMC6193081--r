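#' Physical constants and unit-conversion factors
#'
#' All model kinetics run in internal units: hours for time, molecules/mm3
#' for molecular species and cells/mm3 for cell populations. Clinical units
#' (IU/L for alkaline phosphatase activity, pg/mL for cytokines) appear only
#' at I/O boundaries, through the factors returned here.
#'
#' The factors are derived once from standard physical quantities and kept
#' in a single table: AP molecular mass 160 kDa (dimeric tissue-nonspecific
#' AP) with a specific activity of 1,000 IU/mg, a generic 20 kDa cytokine
#' molecular mass, Avogadro's number, and a 5 L blood / 15 L interstitial
#' fluid volume split for the compartment bookkeeping.
#'
#' @return Named list with elements:
#'   \describe{
#'     \item{ap_iu_per_l_to_molec_mm3}{molecules/mm3 per IU/L of AP activity}
#'     \item{cytokine_pg_ml_to_molec_mm3}{molecules/mm3 per pg/mL of cytokine}
#'     \item{iu_to_blood_conc}{molecules/mm3 of blood per IU of AP dosed}
#'     \item{blood_volume_l, tissue_volume_l}{compartment volumes (L)}
#'     \item{rho_blood_tissue}{blood/tissue volume ratio used for transport}
#'   }
#' @export
#' @examples
#' unit_constants()$ap_iu_per_l_to_molec_mm3
unit_constants <- function() {
  avogadro <- 6.02214076e23    # 1/mol
  ap_mw <- 160000              # g/mol
  ap_iu_per_mg <- 1000         # IU per mg enzyme
  cytokine_mw <- 20000         # g/mol
  blood_volume_l <- 5
  tissue_volume_l <- 15

  # 1 IU/L = 1/ap_iu_per_mg mg/L -> g/L -> molecules/L -> molecules/mm3
  ap_factor <- (1e-3 / ap_iu_per_mg) / ap_mw * avogadro / 1e6
  # 1 pg/mL = 1e-9 g/L
  cy_factor <- 1e-9 / cytokine_mw * avogadro / 1e6

  list(
    avogadro = avogadro,
    ap_mw_g_mol = ap_mw,
    ap_iu_per_mg = ap_iu_per_mg,
    cytokine_mw_g_mol = cytokine_mw,
    blood_volume_l = blood_volume_l,
    tissue_volume_l = tissue_volume_l,
    rho_blood_tissue = blood_volume_l / tissue_volume_l,
    ap_iu_per_l_to_molec_mm3 = ap_factor,
    cytokine_pg_ml_to_molec_mm3 = cy_factor,
    iu_to_blood_conc = ap_factor / blood_volume_l
  )
}

#' Convert AP activity between clinical and internal units
#'
#' Linear, strictly positive factor; the two functions are exact inverses.
#'
#' @param value AP activity in IU/L (for `ap_to_internal`) or concentration
#'   in molecules/mm3 (for `internal_to_ap`). Non-negative.
#' @return Converted value.
#' @export
ap_to_internal <- function(value) {
  if (any(!is.finite(value)) || any(value < 0)) {
    stop("AP activity must be finite and non-negative", call. = FALSE)
  }
  value * unit_constants()$ap_iu_per_l_to_molec_mm3
}

#' @rdname ap_to_internal
#' @export
internal_to_ap <- function(value) {
  value / unit_constants()$ap_iu_per_l_to_molec_mm3
}

#' Convert cytokine concentration between clinical and internal units
#'
#' @param value Cytokine concentration in pg/mL (`cytokine_to_internal`) or
#'   molecules/mm3 (`internal_to_cytokine`). Non-negative.
#' @return Converted value.
#' @export
cytokine_to_internal <- function(value) {
  if (any(!is.finite(value)) || any(value < 0)) {
    stop("cytokine concentration must be finite and non-negative", call. = FALSE)
  }
  value * unit_constants()$cytokine_pg_ml_to_molec_mm3
}

#' @rdname cytokine_to_internal
#' @export
internal_to_cytokine <- function(value) {
  value / unit_constants()$cytokine_pg_ml_to_molec_mm3
}
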