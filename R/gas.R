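#' Total headspace pressure from gauge pressure
#'
#' Total gas pressure is gauge pressure plus one standard atmosphere
#' (101,325 Pa).
#'
#' @param gauge Gauge pressure (Pa); may be negative down to -101,325 Pa.
#' @return Absolute pressure (Pa).
#' @examples
#' total_pressure(50000)  # 151325
#' @export
total_pressure <- function(gauge) {
  p <- gauge + sr_constants$atm_pa
  if (any(p < 0, na.rm = TRUE))
    sr_stop("total_pressure: absolute pressure below 0 Pa")
  p
}

#' Moles of gas in a bottle headspace
#'
#' Ideal-gas moles `n = P V / (R T)` for the bottle headspace, with
#' `R = 8.314 J mol^-1 K^-1` and the temperature converted to kelvin.
#'
#' @param gauge_pressure Gauge pressure (Pa).
#' @param volume_ml Headspace volume (mL), default 60.
#' @param temperature_c Temperature (degrees C), default 39.
#' @return Amount of gas (mol).
#' @examples
#' headspace_moles(0)  # about 2.342e-3 mol at 1 atm, 60 mL, 39 degC
#' @export
headspace_moles <- function(gauge_pressure,
                            volume_ml = sr_constants$headspace_ml,
                            temperature_c = sr_constants$temperature_c) {
  if (any(volume_ml < 0, na.rm = TRUE))
    sr_stop("headspace_moles: volume must be >= 0")
  if (any(temperature_c <= -273.15, na.rm = TRUE))
    sr_stop("headspace_moles: temperature below absolute zero")
  total_pressure(gauge_pressure) * volume_ml * 1e-6 /
    (sr_constants$gas_constant * (temperature_c + 273.15))
}

#' Residual-air fraction of a gas sample from its O2 content
#'
#' Gas samples delivered into evacuated exetainers retain some residual air;
#' the air fraction is estimated as the measured O2 molar fraction divided by
#' 0.2095, the molar proportion of O2 in the atmosphere (anaerobic cultures
#' contribute no O2 of their own).
#'
#' @param o2_fraction Measured O2 molar fraction, in `[0, 0.2095]`. `NA`
#'   values are treated as 0 (no O2 measurement) with a warning.
#' @return Air fraction in `[0, 1]`.
#' @examples
#' residual_air_fraction(0.02095)  # 0.10
#' @export
residual_air_fraction <- function(o2_fraction) {
  if (anyNA(o2_fraction)) {
    warning("residual_air_fraction: missing O2 fraction, assuming no residual air")
    o2_fraction[is.na(o2_fraction)] <- 0
  }
  if (any(o2_fraction < 0))
    sr_stop("residual_air_fraction: O2 fraction must be >= 0")
  if (any(o2_fraction > sr_constants$o2_in_air))
    sr_stop("residual_air_fraction: O2 fraction exceeds 0.2095 (sample would be > 100% air)")
  o2_fraction / sr_constants$o2_in_air
}

#' Correct a measured gas fraction for residual-air dilution
#'
#' Air in the sampling vial only dilutes the culture gas (it carries no CH4
#' or H2 at relevant levels), so the culture-gas fraction is recovered by
#' renormalising over the non-air portion:
#' `corrected = measured / (1 - air_fraction)`. This inverts an air dilution
#' exactly. Corrections that overflow 1 are capped with a warning.
#'
#' @param measured_fraction Measured molar fraction of the species.
#' @param air_fraction Air fraction of the sample, in `[0, 1)`; see
#'   [residual_air_fraction()].
#' @return Corrected molar fraction.
#' @examples
#' correct_species_fraction(0.09, 0.10)  # 0.10
#' @export
correct_species_fraction <- function(measured_fraction, air_fraction) {
  if (any(air_fraction < 0, na.rm = TRUE))
    sr_stop("correct_species_fraction: air fraction must be >= 0")
  if (any(air_fraction >= 1, na.rm = TRUE))
    sr_stop("correct_species_fraction: sample is entirely air, correction impossible",
            class = "sr_correction_impossible")
  out <- measured_fraction / (1 - air_fraction)
  if (any(out > 1, na.rm = TRUE)) {
    warning("correct_species_fraction: corrected fraction > 1, capped at 1")
    out <- pmin(out, 1)
  }
  out
}

#' Headspace CH4 and H2 amounts and H2 partial pressure
#'
#' Converts end-of-transfer gauge pressure and GC molar fractions into
#' species amounts and H2 partial pressure: fractions are corrected for
#' residual air in the exetainer, total headspace moles come from the ideal
#' gas law, species amounts are corrected fraction times total moles, and H2
#' partial pressure is the corrected H2 fraction times total pressure
#' expressed in atm.
#'
#' @param readings Data frame with columns `gauge_pressure_pa`, `frac_ch4`,
#'   `frac_h2` and optionally `frac_o2` (absent or `NA` O2 is treated as no
#'   residual air, with a warning). Optional columns `headspace_volume_ml`
#'   and `temperature_c` override the defaults per row.
#' @return Data frame with columns `total_pressure_pa`, `total_mol`,
#'   `umol_ch4`, `umol_h2`, `ph2_atm`, `air_fraction`, one row per reading.
#' @examples
#' gas_amounts(data.frame(gauge_pressure_pa = 0, frac_ch4 = 0.10,
#'                        frac_h2 = 0.05, frac_o2 = 0))
#' @export
gas_amounts <- function(readings) {
  need <- c("gauge_pressure_pa", "frac_ch4", "frac_h2")
  miss <- setdiff(need, names(readings))
  if (length(miss))
    sr_stop(paste("gas_amounts: missing columns:", paste(miss, collapse = ", ")))
  vol <- if ("headspace_volume_ml" %in% names(readings))
    readings$headspace_volume_ml else sr_constants$headspace_ml
  temp <- if ("temperature_c" %in% names(readings))
    readings$temperature_c else sr_constants$temperature_c
  if (!"frac_o2" %in% names(readings)) {
    warning("gas_amounts: no frac_o2 column, assuming no residual air")
    o2 <- rep(0, nrow(readings))
  } else o2 <- readings$frac_o2
  f_air <- residual_air_fraction(o2)
  ch4 <- correct_species_fraction(readings$frac_ch4, f_air)
  h2 <- correct_species_fraction(readings$frac_h2, f_air)
  p <- total_pressure(readings$gauge_pressure_pa)
  n <- headspace_moles(readings$gauge_pressure_pa, vol, temp)
  data.frame(
    total_pressure_pa = p,
    total_mol = n,
    umol_ch4 = ch4 * n * 1e6,
    umol_h2 = h2 * n * 1e6,
    ph2_atm = h2 * p / sr_constants$atm_pa,
    air_fraction = f_air
  )
}
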