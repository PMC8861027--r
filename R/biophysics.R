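# Big-leaf biophysics: aerodynamic resistance, canopy height, the
# Penman-Monteith forward model and its inversion for canopy conductance,
# Fick's-law leaf-internal CO2, and the Farquhar Vcmax inversion.

#' Aerodynamic resistance from wind speed and canopy geometry
#'
#' Log-profile aerodynamic resistance with momentum roughness length
#' z0 = 0.1 h and zero-plane displacement zd = 0.67 h:
#' ra = ln((zm - zd)/z0)^2 / (ws k^2).
#'
#' @param ws Wind speed (m s-1), > 0.
#' @param zm Measurement height (m).
#' @param h_canopy Canopy height (m); must satisfy zm > 0.67 h + 0.1 h.
#' @return Aerodynamic resistance (s m-1).
#' @export
aerodynamic_resistance <- function(ws, zm, h_canopy) {
  zd <- 0.67 * h_canopy
  z0 <- 0.1 * h_canopy
  if (any(zm <= zd + z0, na.rm = TRUE))
    stop("geometry error: measurement height zm must exceed zd + z0 = 0.77 h")
  if (any(ws <= 0, na.rm = TRUE))
    stop("geometry error: wind speed must be positive")
  log((zm - zd) / z0)^2 / (ws * 0.4^2)
}

#' Canopy height from the near-neutral wind profile
#'
#' h = zm / (0.6 + 0.1 exp(k ws / ustar)), applied per timestep; summarize
#' per site with [site_canopy_height()].
#'
#' @param ws Wind speed (m s-1).
#' @param ustar Friction velocity (m s-1), > 0.
#' @param zm Measurement height (m).
#' @return Canopy height estimate (m); NA where the exponent exceeds 50
#'   (numerically meaningless strong-stability ratios).
#' @export
canopy_height <- function(ws, ustar, zm) {
  if (any(ustar <= 0, na.rm = TRUE)) stop("ustar must be positive")
  expo <- 0.4 * ws / ustar
  h <- zm / (0.6 + 0.1 * exp(expo))
  h[!is.na(expo) & expo > 50] <- NA_real_
  h
}

#' Site-level canopy height: median over near-neutral records
#'
#' @param ws,ustar Vectors of wind speed and friction velocity (m s-1).
#' @param zm Measurement height (m).
#' @param ustar_min Minimum friction velocity admitted as near-neutral
#'   well-mixed conditions (default 0.2 m s-1).
#' @return Scalar canopy height (m).
#' @export
site_canopy_height <- function(ws, ustar, zm, ustar_min = 0.2) {
  ok <- !is.na(ws) & !is.na(ustar) & ustar >= ustar_min & ws > 0
  if (!any(ok)) return(NA_real_)
  stats::median(canopy_height(ws[ok], ustar[ok], zm), na.rm = TRUE)
}

#' Forward big-leaf Penman-Monteith latent heat flux
#'
#' lambda E = [Delta (Rn - G) + rho cp VPD / ra] / [Delta + gamma (1 + rs/ra)]
#' with rs = 1/gc. Delta and gamma are evaluated at ta; VPD in kPa is
#' converted to Pa internally so the result is W m-2.
#'
#' @param gc_ms Canopy (surface) conductance (m s-1).
#' @param ra Aerodynamic resistance (s m-1).
#' @param rn Net radiation (W m-2).
#' @param g_soil Soil heat flux (W m-2).
#' @param ta Air temperature (degC).
#' @param vpd Vapor pressure deficit (kPa).
#' @param pressure_kpa Air pressure (kPa).
#' @return Latent heat flux (W m-2).
#' @export
penman_monteith <- function(gc_ms, ra, rn, g_soil, ta, vpd,
                            pressure_kpa = 101.325) {
  delta <- esat_slope(ta) * 1000          # Pa K-1
  gamma <- psychrometric(ta, pressure_kpa) * 1000
  rho <- air_density(ta, pressure_kpa)
  cp <- biophys_constants()$cp
  num <- delta * (rn - g_soil) + rho * cp * (vpd * 1000) / ra
  num / (delta + gamma * (1 + 1 / (gc_ms * ra)))
}

#' Invert the Penman-Monteith equation for canopy conductance
#'
#' Solves the forward big-leaf equation for the surface conductance that
#' reproduces the observed latent heat flux. Records where the implied
#' conductance is non-positive (e.g. LE at or above the aerodynamically
#' unlimited rate, or vanishing VPD) are returned as NA.
#'
#' @inheritParams penman_monteith
#' @param le Observed latent heat flux (W m-2), > 0.
#' @return Canopy conductance (m s-1), NA where degenerate.
#' @export
invert_penman_monteith <- function(le, rn, g_soil, ta, vpd, ra,
                                   pressure_kpa = 101.325) {
  delta <- esat_slope(ta) * 1000
  gamma <- psychrometric(ta, pressure_kpa) * 1000
  rho <- air_density(ta, pressure_kpa)
  cp <- biophys_constants()$cp
  num <- delta * (rn - g_soil) + rho * cp * (vpd * 1000) / ra
  denom <- num / le - (delta + gamma)
  gc <- gamma / (ra * denom)
  bad <- !is.finite(gc) | gc <= 0 | le <= 0 | vpd <= 0 | ra <= 0
  gc[bad] <- NA_real_
  gc
}

#' Convert conductance from m s-1 to mol m-2 s-1
#' @param gc_ms Conductance (m s-1).
#' @param ta Air temperature (degC).
#' @param pressure_kpa Air pressure (kPa).
#' @export
gc_to_mol <- function(gc_ms, ta, pressure_kpa = 101.325) {
  gc_ms * molar_density(ta, pressure_kpa)
}

#' Leaf-internal CO2 mole fraction via Fick's law
#'
#' ci = ca - GPP (1.6/Gc + ra_mol), all CO2 quantities as mole fractions
#' (umol mol-1). Intended for midday (11:00-14:00), high-radiation records.
#'
#' @param gpp GPP (umol CO2 m-2 s-1).
#' @param gc_mol Canopy conductance to water vapor (mol m-2 s-1).
#' @param ra_mol Aerodynamic resistance in molar units (m2 s mol-1);
#'   convert from s m-1 by dividing by [molar_density()].
#' @param ca Ambient CO2 mole fraction (umol mol-1).
#' @param ta Air temperature (degC), used to flag ci below the CO2
#'   compensation point.
#' @return ci (umol mol-1); NA where gc_mol <= 0 or outside (Gamma*, ca).
#' @export
leaf_internal_co2 <- function(gpp, gc_mol, ra_mol = 0, ca = 400, ta = 25) {
  ci <- ca - gpp * (1.6 / gc_mol + ra_mol)
  ci[!is.na(gc_mol) & gc_mol <= 0] <- NA_real_
  gs <- gamma_star(ta)
  ci[!is.na(ci) & (ci <= gs | ci > ca)] <- NA_real_
  ci
}

arrhenius <- function(k25, ha, ta) {
  tk <- ta + 273.15
  k25 * exp(ha * (tk - 298.15) / (298.15 * 8.314 * tk))
}

#' Temperature-dependent Rubisco kinetics (Bernacchi responses)
#'
#' @param ta Air temperature (degC).
#' @param const Constant set from [biophys_constants()].
#' @return `gamma_star`: CO2 compensation point without day respiration
#'   (umol mol-1); `michaelis_k`: effective Michaelis-Menten coefficient
#'   K = Kc (1 + O/Ko) (umol mol-1).
#' @export
gamma_star <- function(ta, const = biophys_constants()) {
  arrhenius(const$gammastar25, const$ha_gammastar, ta)
}

#' @rdname gamma_star
#' @export
michaelis_k <- function(ta, const = biophys_constants()) {
  kc <- arrhenius(const$kc25, const$ha_kc, ta)
  ko <- arrhenius(const$ko25, const$ha_ko, ta)
  kc * (1 + const$o2 / ko)
}

#' Rubisco-limited assimilation (forward Farquhar model)
#'
#' Amax = Vcmax (ci - Gamma*) / (ci + K). Used as the oracle for
#' [invert_vcmax()].
#'
#' @param vcmax Maximum carboxylation rate (umol m-2 s-1) at ta.
#' @param ci Leaf-internal CO2 (umol mol-1).
#' @param ta Air temperature (degC).
#' @export
forward_amax <- function(vcmax, ci, ta) {
  vcmax * (ci - gamma_star(ta)) / (ci + michaelis_k(ta))
}

#' Invert the Farquhar model for Vcmax and standardize to 25 degC
#'
#' Vcmax = Amax (ci + K)/(ci - Gamma*); Vcmax25 divides out the Arrhenius
#' factor with the carboxylation activation energy, so at ta = 25 degC
#' Vcmax25 equals Vcmax exactly.
#'
#' @param amax Light-saturated assimilation (umol m-2 s-1).
#' @param ci Leaf-internal CO2 (umol mol-1), must exceed Gamma*(ta).
#' @param ta Air temperature (degC).
#' @param const Constant set from [biophys_constants()].
#' @return data.frame with columns `vcmax` and `vcmax25` (umol m-2 s-1);
#'   NA where ci <= Gamma* (negative carboxylation regime).
#' @export
invert_vcmax <- function(amax, ci, ta, const = biophys_constants()) {
  gs <- gamma_star(ta, const)
  vc <- amax * (ci + michaelis_k(ta, const)) / (ci - gs)
  vc[!is.na(ci) & ci <= gs] <- NA_real_
  vc25 <- vc / arrhenius(1, const$ha_vcmax, ta)
  data.frame(vcmax = vc, vcmax25 = vc25)
}

#' Intrinsic water-use efficiency
#'
#' iWUE = GPP / Gc (umol CO2 per mol H2O).
#'
#' @param gpp GPP (umol m-2 s-1).
#' @param gc_mol Canopy conductance (mol m-2 s-1), > 0.
#' @export
iwue <- function(gpp, gc_mol) {
  out <- gpp / gc_mol
  out[!is.na(gc_mol) & gc_mol <= 0] <- NA_real_
  out
}
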