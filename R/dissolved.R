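#' Henry's-law solubility constants
#'
#' Default two-parameter van 't Hoff constants for CH4 and CO2 in fresh
#' water: the solubility at 298.15 K (`H0`, mol m-3 Pa-1) and the
#' temperature-dependence enthalpy parameter (`B`, K). These are standard
#' compilation values; override them to use a different parameterisation.
#'
#' @return A list with one element per gas, each a list `H0`, `B`.
#' @export
henry_constants <- function() {
  list(CH4 = list(H0 = 1.4e-5, B = 1900),
       CO2 = list(H0 = 3.3e-4, B = 2400))
}

#' Henry's-law solubility at a given temperature
#'
#' Evaluates `H(T) = H0 * exp(B * (1/T - 1/298.15))` with `T` in kelvin.
#' Solubility decreases with temperature (`B > 0`). Temperatures outside
#' the calibrated range -2 to 40 deg C are clamped with a warning.
#'
#' @param gas `"CH4"` or `"CO2"`.
#' @param temperature_c Water temperature, deg C (vectorised).
#' @param constants Solubility constants, see [henry_constants()].
#' @return Solubility in mol m-3 Pa-1.
#' @examples
#' henry_solubility("CH4", 5)
#' @export
henry_solubility <- function(gas, temperature_c,
                             constants = henry_constants()) {
  gas <- match_gas(gas)
  if (is.null(constants[[gas]])) stop("no Henry constants for gas ", gas)
  if (any(temperature_c < -2 | temperature_c > 40)) {
    warning("temperature outside -2..40 C; clamping")
    temperature_c <- pmin(pmax(temperature_c, -2), 40)
  }
  tk <- temperature_c + .KELVIN0
  constants[[gas]]$H0 * exp(constants[[gas]]$B * (1 / tk - 1 / .T_REF))
}

#' Dissolved gas concentration from a headspace-equilibration sample
#'
#' Inverts the closed-syringe mass balance of the headspace equilibration
#' method: a water sample is equilibrated against an initially gas-free N2
#' headspace, and the analyte measured in the headspace afterwards. All of
#' the analyte originally dissolved in the water is then split between the
#' headspace (ideal gas at the equilibration temperature and site pressure)
#' and the water (Henry's law at the headspace partial pressure):
#'
#'   C_w * V_w = x * P * V_hs / (R * T)  +  H(T) * x * P * V_w
#'
#' with `x` the measured headspace mixing ratio (as a fraction) and `P` the
#' total pressure. The balance is linear in `x`, so doubling the headspace
#' reading doubles the recovered concentration.
#'
#' @param headspace_ppm Post-equilibration headspace mixing ratio, ppm.
#' @param gas `"CH4"` or `"CO2"`.
#' @param temperature_c Equilibration (field water) temperature, deg C.
#' @param pressure_kpa Site air pressure, kPa.
#' @param water_volume_ml,headspace_volume_ml Syringe volumes, mL
#'   (defaults 50/50).
#' @param constants Solubility constants, see [henry_constants()].
#' @return Dissolved concentration `C_w` in mmol m-3 (vectorised).
#' @seealso [dissolved_to_headspace()] for the forward calculation.
#' @export
headspace_to_dissolved <- function(headspace_ppm, gas, temperature_c,
                                   pressure_kpa,
                                   water_volume_ml = 50,
                                   headspace_volume_ml = 50,
                                   constants = henry_constants()) {
  if (any(water_volume_ml <= 0) || any(headspace_volume_ml <= 0))
    stop("syringe volumes must be positive")
  if (any(headspace_ppm < 0)) stop("headspace mixing ratio must be >= 0")
  h <- henry_solubility(gas, temperature_c, constants)
  tk <- temperature_c + .KELVIN0
  p_pa <- pressure_kpa * 1000
  v_w <- water_volume_ml * 1e-6   # m^3
  v_hs <- headspace_volume_ml * 1e-6
  p_gas <- headspace_ppm * 1e-6 * p_pa  # partial pressure, Pa
  n_headspace <- p_gas * v_hs / (.R_GAS * tk)  # mol
  n_aqueous <- h * p_gas * v_w                 # mol
  (n_headspace + n_aqueous) / v_w * 1000       # mmol m-3
}

#' Equilibrium headspace mixing ratio for a known dissolved concentration
#'
#' Forward counterpart of [headspace_to_dissolved()]: given the dissolved
#' concentration in the water sample before equilibration, returns the
#' headspace mixing ratio the syringe balance predicts after equilibration.
#' Used by the synthetic-survey generator and as a round-trip check.
#'
#' @inheritParams headspace_to_dissolved
#' @param c_w Dissolved concentration before equilibration, mmol m-3.
#' @return Equilibrium headspace mixing ratio, ppm.
#' @export
dissolved_to_headspace <- function(c_w, gas, temperature_c, pressure_kpa,
                                   water_volume_ml = 50,
                                   headspace_volume_ml = 50,
                                   constants = henry_constants()) {
  if (any(c_w < 0)) stop("dissolved concentration must be >= 0")
  h <- henry_solubility(gas, temperature_c, constants)
  tk <- temperature_c + .KELVIN0
  p_pa <- pressure_kpa * 1000
  v_w <- water_volume_ml * 1e-6
  v_hs <- headspace_volume_ml * 1e-6
  denom <- 1e-6 * p_pa * (v_hs / (.R_GAS * tk) + h * v_w)
  c_w * 1e-3 * v_w / denom
}

#' Dissolved concentration at equilibrium with the local atmosphere
#'
#' `C_eq = H(T) * x_atm * P` on a partial-pressure basis, so the
#' equilibrium concentration falls with site pressure: at 61 kPa a lake
#' equilibrates with ~60% of the dissolved gas it would hold at sea level.
#'
#' @inheritParams headspace_to_dissolved
#' @param atm_ppm Atmospheric mixing ratio at the site, ppm.
#' @return `C_eq` in mmol m-3 (vectorised).
#' @examples
#' equilibrium_concentration("CH4", 1.9, 10, 61)
#' @export
equilibrium_concentration <- function(gas, atm_ppm, temperature_c,
                                      pressure_kpa,
                                      constants = henry_constants()) {
  if (any(atm_ppm < 0)) stop("atmospheric mixing ratio must be >= 0")
  if (any(pressure_kpa <= 0)) stop("pressure must be positive")
  h <- henry_solubility(gas, temperature_c, constants)
  h * atm_ppm * 1e-6 * (pressure_kpa * 1000) * 1000  # mmol m-3
}

#' Gas saturation relative to atmospheric equilibrium
#'
#' `S = 100 * C_w / C_eq` in percent; values above 100% mean the lake
#' outgasses. A zero equilibrium concentration makes saturation undefined
#' and is flagged with `NA` and a warning.
#'
#' @param c_w Dissolved concentration, mmol m-3.
#' @param c_eq Equilibrium concentration, mmol m-3.
#' @return Saturation in percent (vectorised).
#' @examples
#' saturation(29.21, 1)  # 2921 %
#' @export
saturation <- function(c_w, c_eq) {
  if (any(c_w < 0, na.rm = TRUE) || any(c_eq < 0, na.rm = TRUE))
    stop("concentrations must be >= 0")
  out <- ifelse(c_eq > 0, 100 * c_w / c_eq, NA_real_)
  if (any(c_eq == 0, na.rm = TRUE))
    warning("saturation undefined where C_eq = 0; flagged as NA")
  out
}

#' Dissolved concentrations and saturation for a table of water samples
#'
#' Applies [headspace_to_dissolved()], [equilibrium_concentration()] and
#' [saturation()] row-wise to a long water-sample table (one row per
#' lake-campaign-gas) as produced by [generate_survey()].
#'
#' @param water_samples Data frame with columns `cluster_id`, `lake_id`,
#'   `campaign`, `gas`, `headspace_ppm`, `water_temperature` (deg C),
#'   `air_pressure` (kPa), `atm_ppm`, `water_volume_ml`,
#'   `headspace_volume_ml`.
#' @param constants Solubility constants, see [henry_constants()].
#' @return The key columns plus `c_w`, `c_eq` (mmol m-3) and
#'   `saturation_pct`.
#' @export
dissolved_concentrations <- function(water_samples,
                                     constants = henry_constants()) {
  ws <- water_samples
  c_w <- c_eq <- numeric(nrow(ws))
  for (g in unique(ws$gas)) {
    i <- ws$gas == g
    c_w[i] <- headspace_to_dissolved(ws$headspace_ppm[i], g,
                                     ws$water_temperature[i],
                                     ws$air_pressure[i],
                                     ws$water_volume_ml[i],
                                     ws$headspace_volume_ml[i], constants)
    c_eq[i] <- equilibrium_concentration(g, ws$atm_ppm[i],
                                         ws$water_temperature[i],
                                         ws$air_pressure[i], constants)
  }
  data.frame(cluster_id = ws$cluster_id, lake_id = ws$lake_id,
             campaign = ws$campaign, gas = ws$gas,
             c_w = c_w, c_eq = c_eq,
             saturation_pct = saturation(c_w, c_eq))
}
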