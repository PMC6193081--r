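#' Treatment protocol: AP bolus plus continuous infusion
#'
#' Describes the supplemented-AP regimen of one treatment arm: an
#' intravenous bolus at surgery onset (t = 0) followed by a constant-rate
#' infusion. The clinically tested regimen is a 1,000 IU bolus followed by
#' 8,000 IU infused over 8 h (9,000 IU in total); the placebo arm is the
#' all-zero protocol. `scale` multiplies every dose for regimen-scaling
#' experiments.
#'
#' @param bolus_iu Bolus dose at t = 0 (IU), >= 0.
#' @param infusion_total_iu Total infused dose (IU), >= 0.
#' @param infusion_duration_h Infusion duration (h); must be > 0 whenever
#'   `infusion_total_iu > 0`.
#' @param infusion_rate_iu_per_kg_h Optional per-kg rate (IU/kg/h),
#'   informational only: totals take precedence.
#' @param patient_weight_kg Optional weight (kg), informational.
#' @param scale Multiplicative regimen scale (1 = as specified).
#' @return Object of class `treatment_protocol`.
#' @export
#' @examples
#' total_dose(appired2_protocol())   # 9000
treatment_protocol <- function(bolus_iu = 0, infusion_total_iu = 0,
                               infusion_duration_h = 8,
                               infusion_rate_iu_per_kg_h = NULL,
                               patient_weight_kg = NULL,
                               scale = 1) {
  doses <- c(bolus_iu = bolus_iu, infusion_total_iu = infusion_total_iu,
             scale = scale)
  if (any(!is.finite(doses)) || any(doses < 0)) {
    stop("doses and scale must be finite and non-negative", call. = FALSE)
  }
  if (infusion_total_iu > 0 && infusion_duration_h <= 0) {
    stop("infusion_duration_h must be > 0 when infusion_total_iu > 0",
         call. = FALSE)
  }
  structure(
    list(bolus_iu = bolus_iu,
         infusion_total_iu = infusion_total_iu,
         infusion_duration_h = infusion_duration_h,
         infusion_rate_iu_per_kg_h = infusion_rate_iu_per_kg_h,
         patient_weight_kg = patient_weight_kg,
         scale = scale),
    class = "treatment_protocol")
}

#' @rdname treatment_protocol
#' @export
placebo_protocol <- function() treatment_protocol(0, 0, 8, scale = 1)

#' The bolus + 8 h infusion regimen of the validated supplementation arm
#' @param scale Regimen scale (1, 2, 3, ...).
#' @rdname treatment_protocol
#' @export
appired2_protocol <- function(scale = 1) {
  treatment_protocol(bolus_iu = 1000, infusion_total_iu = 8000,
                     infusion_duration_h = 8,
                     infusion_rate_iu_per_kg_h = 5.6, scale = scale)
}

#' @export
print.treatment_protocol <- function(x, ...) {
  cat(sprintf(
    "<treatment_protocol> bolus %g IU + %g IU over %g h (scale %g, total %g IU)\n",
    x$bolus_iu, x$infusion_total_iu, x$infusion_duration_h, x$scale,
    total_dose(x)))
  invisible(x)
}

#' Infusion input rate at a given time
#'
#' Piecewise-constant source: `infusion_total_iu / infusion_duration_h`
#' (times `scale`) during the infusion window, zero after.
#'
#' @param t Time since surgery onset (h), >= 0. Vectorised.
#' @param protocol A [treatment_protocol()].
#' @return Infusion rate (IU/h).
#' @export
infusion_rate_at <- function(t, protocol) {
  stopifnot(inherits(protocol, "treatment_protocol"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (protocol$infusion_total_iu <= 0) return(rep(0, length(t)))
  rate <- protocol$infusion_total_iu / protocol$infusion_duration_h
  ifelse(t < protocol$infusion_duration_h, rate * protocol$scale, 0)
}

#' Total supplemented AP of a protocol
#'
#' Bolus plus infused total, multiplied by the regimen scale.
#'
#' @param protocol A [treatment_protocol()].
#' @return Total dose (IU).
#' @export
total_dose <- function(protocol) {
  stopifnot(inherits(protocol, "treatment_protocol"))
  (protocol$bolus_iu + protocol$infusion_total_iu) * protocol$scale
}

#' Rescale a protocol
#' @param protocol A [treatment_protocol()].
#' @param scale New multiplicative scale.
#' @return Rescaled protocol.
#' @export
scale_protocol <- function(protocol, scale) {
  protocol$scale <- scale
  protocol
}
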