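# Unit-conversion chain: ppm CO2 excess -> uL/h -> uW -> mass-corrected uW.
# Every step is linear in the signal, so means commute with the chain.

#' Oxyjoule energy coefficient
#'
#' Energy released per millilitre of O2 consumed at a given respiratory
#' quotient, using the oxyjoule relation (16 + 5.164 RQ) J/mL. At RQ = 1
#' (pure carbohydrate catabolism, V̇O2 = V̇CO2) this is 21.164 J/mL.
#'
#' @param rq Respiratory quotient (CO2 produced / O2 consumed), > 0.
#' @return Energy coefficient in J per mL O2.
#' @export
#' @examples
#' oxyjoule_coefficient(1) # 21.164
oxyjoule_coefficient <- function(rq = 1) {
  stopifnot(is.numeric(rq), length(rq) == 1, rq > 0)
  16 + 5.164 * rq
}

#' Convert CO2 excess (ppm) to volumetric flux (uL/h)
#'
#' At a known flow rate, a CO2 mole-fraction excess translates directly into
#' a volumetric production rate:
#' flux = ppm x 1e-6 x flow (mL/min) x 60 (min/h) x 1000 (uL/mL)
#'      = ppm x flow x 0.06.
#'
#' @param co2_excess_ppm Numeric vector of baseline-corrected CO2 excess, ppm.
#' @param flow_ml_min STP-corrected flow rate in mL/min, > 0.
#' @return V̇CO2 in uL per hour (same length as `co2_excess_ppm`).
#' @export
#' @examples
#' ppm_to_flux(1, 50) # 3.0 uL/h
ppm_to_flux <- function(co2_excess_ppm, flow_ml_min) {
  stopifnot(is.numeric(co2_excess_ppm), is.numeric(flow_ml_min),
            length(flow_ml_min) == 1)
  if (!is.finite(flow_ml_min) || flow_ml_min <= 0) {
    stop("`flow_ml_min` must be a positive finite number, got ", flow_ml_min)
  }
  co2_excess_ppm * flow_ml_min * 0.06
}

#' Convert CO2 flux (uL/h) to metabolic power (uW)
#'
#' V̇O2 = V̇CO2 / RQ; power(uW) = V̇O2 (uL/h) x coef (J/mL) x 1e-3 (mL/uL)
#' / 3600 (s/h) x 1e6 (uW/W). At RQ = 1 with the oxyjoule coefficient this
#' reduces to V̇CO2 x 21.164 / 3.6 = V̇CO2 x 5.8789 uW per uL/h.
#'
#' Baseline-corrected traces legitimately contain negative excursions
#' (analyzer noise around zero); the segment pipeline passes
#' `allow_negative = TRUE` so that averaging is not biased upward. At the
#' user surface a negative flux is rejected by default.
#'
#' @param vco2_ul_h CO2 production in uL/h.
#' @param rq Respiratory quotient, > 0. Default 1.
#' @param joule_coefficient Energy per mL O2 in J/mL; defaults to
#'   [oxyjoule_coefficient()] at `rq`.
#' @param allow_negative Permit negative fluxes (internal pipeline use).
#' @return Metabolic power in uW.
#' @export
#' @examples
#' flux_to_power(3) # 17.637 uW
flux_to_power <- function(vco2_ul_h, rq = 1,
                          joule_coefficient = oxyjoule_coefficient(rq),
                          allow_negative = FALSE) {
  stopifnot(is.numeric(vco2_ul_h), rq > 0, joule_coefficient > 0)
  if (!allow_negative && any(vco2_ul_h < 0, na.rm = TRUE)) {
    stop("negative CO2 flux supplied; use allow_negative = TRUE if this is ",
         "a baseline-corrected series with noise excursions below zero")
  }
  (vco2_ul_h / rq) * joule_coefficient / 3.6
}

#' Allometric mass correction of metabolic power
#'
#' Divides power by live mass raised to the inter-specific scaling exponent
#' for tracheate arthropods (0.856), yielding a mass-independent metabolic
#' rate in uW mg^-0.856.
#'
#' @param power_uW Metabolic power in uW.
#' @param mass_mg Live mass in mg, > 0.
#' @param exponent Allometric exponent. Default 0.856.
#' @return Mass-corrected power, uW mg^-exponent.
#' @export
#' @examples
#' mass_correct(10, 2) # 10 / 2^0.856 = 5.525
mass_correct <- function(power_uW, mass_mg, exponent = 0.856) {
  stopifnot(is.numeric(power_uW), is.numeric(mass_mg), length(mass_mg) == 1,
            is.numeric(exponent), length(exponent) == 1)
  if (!is.finite(mass_mg) || mass_mg <= 0) {
    stop("`mass_mg` must be positive, got ", mass_mg)
  }
  power_uW / mass_mg^exponent
}

# exact inverse of the ppm -> uW chain, used by the synthetic generator
power_to_ppm <- function(power_uW, flow_ml_min, rq = 1,
                         joule_coefficient = oxyjoule_coefficient(rq)) {
  power_uW * rq / (joule_coefficient / 3.6) / (flow_ml_min * 0.06)
}

#' Absolute difference sum (ADS) of an activity channel
#'
#' Cumulative sum of absolute differences between adjacent samples:
#' ADS\[1\] = 0, ADS\[k\] = sum over i <= k of |x\[i\] - x\[i-1\]|.
#' Non-decreasing by construction and invariant to constant offsets.
#'
#' @param activity Numeric vector, length >= 2.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' compute_ads(c(0, 1, 1, 3)) # 0 1 1 3
compute_ads <- function(activity) {
  stopifnot(is.numeric(activity))
  if (length(activity) < 2) {
    stop("activity series must have at least 2 samples")
  }
  c(0, cumsum(abs(diff(activity))))
}

#' Activity index from an ADS series
#'
#' index = (max(ADS) - min(ADS)) / N x 60, the mean absolute first
#' difference of the activity channel per minute of recording. N is the
#' number of 1-Hz samples (seconds) in the window.
#'
#' @param ads ADS series as returned by [compute_ads()].
#' @param n Number of samples; must equal `length(ads)`.
#' @return Non-negative scalar index (activity units per minute).
#' @export
#' @examples
#' activity_index(compute_ads(c(0, 1, 1, 3)), 4) # 3/4*60 = 45
activity_index <- function(ads, n) {
  stopifnot(is.numeric(ads), length(ads) >= 2)
  if (n != length(ads)) {
    stop("`n` (", n, ") does not match the ADS series length (",
         length(ads), ")")
  }
  (max(ads) - min(ads)) / n * 60
}
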