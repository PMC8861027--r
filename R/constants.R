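#' Biophysical constants
#'
#' Returns the set of physical and biochemical constants used by the
#' conductance and photosynthesis inversions. Michaelis-Menten and CO2
#' compensation-point parameters (25 degC values and activation energies)
#' follow the Bernacchi in-vivo temperature responses; they are centralized
#' here so every consumer shares one audited set.
#'
#' @param pressure_kpa Air pressure in kPa used when a site reports none.
#' @return A list with components:
#'   \describe{
#'     \item{k_vk}{von Karman constant (0.4, dimensionless)}
#'     \item{cp}{specific heat of dry air at constant pressure (J kg-1 K-1)}
#'     \item{r_gas}{universal gas constant (J mol-1 K-1)}
#'     \item{r_dry}{specific gas constant of dry air (J kg-1 K-1)}
#'     \item{pressure_kpa}{default air pressure (kPa)}
#'     \item{vpd0}{VPD threshold below which the light-response plateau is
#'       not reduced (kPa)}
#'     \item{ca}{ambient CO2 mole fraction (umol mol-1)}
#'     \item{o2}{O2 mole fraction (mmol mol-1)}
#'     \item{kc25, ko25, gammastar25}{Rubisco kinetics at 25 degC
#'       (umol mol-1, mmol mol-1, umol mol-1)}
#'     \item{ha_kc, ha_ko, ha_gammastar, ha_vcmax}{activation energies
#'       (J mol-1)}
#'   }
#' @export
biophys_constants <- function(pressure_kpa = 101.325) {
  list(
    k_vk = 0.4,
    cp = 1013,              # J kg-1 K-1, moist-air value used in FAO-56
    r_gas = 8.314,
    r_dry = 287.05,
    pressure_kpa = pressure_kpa,
    vpd0 = 1.0,
    ca = 400,
    o2 = 210,
    kc25 = 404.9,
    ko25 = 278.4,
    gammastar25 = 42.75,
    ha_kc = 79430,
    ha_ko = 36380,
    ha_gammastar = 37830,
    ha_vcmax = 65330
  )
}

#' Saturation vapor pressure (kPa) at air temperature ta (degC)
#' @param ta Air temperature, degC.
#' @return Saturation vapor pressure, kPa (Tetens/Magnus form).
#' @export
esat_kpa <- function(ta) 0.6108 * exp(17.27 * ta / (ta + 237.3))

#' Slope of the saturation vapor pressure curve (kPa K-1)
#' @param ta Air temperature, degC.
#' @return d(esat)/dT at ta, kPa per K.
#' @export
esat_slope <- function(ta) 4098 * esat_kpa(ta) / (ta + 237.3)^2

#' Latent heat of vaporization of water (J kg-1), linear in temperature
#' @param ta Air temperature, degC.
#' @export
latent_heat <- function(ta) (2.501 - 0.00237 * ta) * 1e6

#' Psychrometric constant (kPa K-1)
#' @param ta Air temperature, degC.
#' @param pressure_kpa Air pressure, kPa.
#' @export
psychrometric <- function(ta, pressure_kpa = 101.325) {
  biophys_constants()$cp * pressure_kpa / (0.622 * latent_heat(ta))
}

#' Dry-air density (kg m-3) from the ideal gas law
#' @param ta Air temperature, degC.
#' @param pressure_kpa Air pressure, kPa.
#' @export
air_density <- function(ta, pressure_kpa = 101.325) {
  pressure_kpa * 1000 / (287.05 * (ta + 273.15))
}

#' Molar density of air (mol m-3); 40.87 at 101.325 kPa and 25 degC
#' @param ta Air temperature, degC.
#' @param pressure_kpa Air pressure, kPa.
#' @export
molar_density <- function(ta, pressure_kpa = 101.325) {
  pressure_kpa * 1000 / (8.314 * (ta + 273.15))
}
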