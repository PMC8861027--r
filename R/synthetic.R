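# Synthetic multi-site flux-tower generator. Drivers (radiation,
# temperature, soil moisture, VPD, wind) follow simple seasonal/diurnal
# processes with land-atmosphere covariation between SWC and VPD; fluxes
# are produced by a known, analytically differentiable GPP response
# surface and the forward Penman-Monteith equation, so every downstream
# inversion and sensitivity estimate has an exact oracle.

#' Ground-truth parameters of the synthetic GPP response surface
#'
#' The biochemical capacity is a smooth unimodal bump in SWC (declining
#' toward dry soils, water stress, and above `swc_opt`, a
#' waterlogging-like decline), multiplied by an exponential VPD limitation
#' above `vpd0`, and passed through a rectangular-hyperbola light
#' response. The bump is a Gaussian with separate widths on the dry and
#' wet side of the optimum (continuously differentiable: the derivative
#' vanishes at the peak).
#'
#' @param swc_opt Volumetric SWC (%) at which capacity peaks.
#' @param swc_lo SWC (%) stress threshold below which canopy conductance
#'   is additionally down-regulated (must be < `swc_opt`); capacity itself
#'   declines continuously below the optimum.
#' @param swc_width Gaussian width (%) of the capacity decline on the dry
#'   side of the optimum.
#' @param swc_width_hi Gaussian width (%) of the waterlogging decline on
#'   the wet side.
#' @param swc_floor Fraction of peak capacity retained far from the
#'   optimum (the bump modulates only the remaining share), in [0, 1).
#' @param ta_opt Air temperature (degC) of peak capacity.
#' @param ta_width Gaussian width (degC) of the temperature response.
#' @param amax_peak Peak biochemical capacity (umol CO2 m-2 s-1).
#' @param vpd_decay Exponential VPD decay rate (kPa-1), >= 0.
#' @param vpd0 VPD decay onset (kPa).
#' @param alpha_true Canopy quantum yield (umol CO2 per W shortwave).
#' @param g1 Stomatal slope (kPa^0.5).
#' @param g0 Residual conductance (mol m-2 s-1).
#' @param reco_base Base ecosystem respiration at 15 degC (umol m-2 s-1).
#' @param q10 Respiration temperature sensitivity (dimensionless).
#' @param noise_sd_rel Relative (multiplicative) flux noise SD.
#' @param ar1_phi Lag-1 coefficient of the daily SWC anomaly process,
#'   in [0, 1).
#' @param qc_bad_frac Fraction of half-hours flagged as poor gap-fill
#'   (QC >= 2).
#' @param n_sites Number of sites.
#' @param n_days Days per site (>= 30).
#' @param step_min Timestep in minutes (30 or 60).
#' @param seed Base RNG seed; site k uses seed + 1009 k.
#' @return List of class `truth_params`.
#' @export
truth_params <- function(swc_opt = 26, swc_lo = 18, swc_width = 9,
                         swc_width_hi = 7, swc_floor = 0.6,
                         ta_opt = 22, ta_width = 9,
                         amax_peak = 25, vpd_decay = 0.4, vpd0 = 1.0,
                         alpha_true = 0.08, g1 = 3.0, g0 = 0.01,
                         reco_base = 2, q10 = 2, noise_sd_rel = 0.1,
                         ar1_phi = 0.85, qc_bad_frac = 0.05,
                         n_sites = 20, n_days = 1095, step_min = 30,
                         seed = 42) {
  p <- list(swc_opt = swc_opt, swc_lo = swc_lo, swc_width = swc_width,
            swc_width_hi = swc_width_hi, swc_floor = swc_floor,
            ta_opt = ta_opt,
            ta_width = ta_width, amax_peak = amax_peak,
            vpd_decay = vpd_decay, vpd0 = vpd0,
            alpha_true = alpha_true, g1 = g1, g0 = g0,
            reco_base = reco_base, q10 = q10, noise_sd_rel = noise_sd_rel,
            ar1_phi = ar1_phi, qc_bad_frac = qc_bad_frac,
            n_sites = n_sites, n_days = n_days, step_min = step_min,
            seed = seed)
  if (!(swc_lo < swc_opt)) stop("invalid parameter 'swc_lo': must be < swc_opt")
  if (swc_floor < 0 || swc_floor >= 1)
    stop("invalid parameter 'swc_floor': must be in [0, 1)")
  if (vpd_decay < 0) stop("invalid parameter 'vpd_decay': must be >= 0")
  if (amax_peak <= 0) stop("invalid parameter 'amax_peak': must be > 0")
  if (ar1_phi < 0 || ar1_phi >= 1) stop("invalid parameter 'ar1_phi': must be in [0, 1)")
  if (noise_sd_rel < 0) stop("invalid parameter 'noise_sd_rel': must be >= 0")
  if (n_days < 30) stop("invalid parameter 'n_days': must be >= 30")
  if (!step_min %in% c(30, 60)) stop("invalid parameter 'step_min': must be 30 or 60")
  structure(p, class = "truth_params")
}

#' @export
print.truth_params <- function(x, ...) {
  cat("Synthetic ground truth:\n")
  cat(sprintf("  SWC response: peak at %g%% (widths %g/%g%%), Amax %g, stress threshold %g%%\n",
              x$swc_opt, x$swc_width, x$swc_width_hi, x$amax_peak, x$swc_lo))
  cat(sprintf("  VPD decay %g kPa-1 above %g kPa; alpha %g, g1 %g, g0 %g\n",
              x$vpd_decay, x$vpd0, x$alpha_true, x$g1, x$g0))
  cat(sprintf("  %d sites x %d days at %d min, noise %g, AR1 %g, seed %d\n",
              x$n_sites, x$n_days, x$step_min, x$noise_sd_rel, x$ar1_phi,
              x$seed))
  invisible(x)
}

# unimodal SWC capacity: a piecewise-width Gaussian bump peaking exactly
# at swc_opt, with width swc_width on the dry side and swc_width_hi on the
# wet side (C1 at the peak where the derivative vanishes).
swc_capacity <- function(swc, params) {
  w <- ifelse(swc < params$swc_opt, params$swc_width, params$swc_width_hi)
  bump <- exp(-0.5 * ((swc - params$swc_opt) / w)^2)
  params$amax_peak * (params$swc_floor + (1 - params$swc_floor) * bump)
}

vpd_multiplier <- function(vpd, params) {
  exp(-params$vpd_decay * pmax(0, vpd - params$vpd0))
}

ta_multiplier <- function(ta, params) {
  exp(-0.5 * ((ta - params$ta_opt) / params$ta_width)^2)
}

#' True GPP of the synthetic surface
#'
#' GPP = alpha Rg B / (alpha Rg + B) with B = A*(SWC) m(VPD).
#'
#' @param params A [truth_params()] object.
#' @param swc Volumetric SWC (%).
#' @param vpd Vapor pressure deficit (kPa).
#' @param rg Incoming shortwave radiation (W m-2).
#' @param ta Air temperature (degC).
#' @return GPP (umol m-2 s-1).
#' @export
gpp_true <- function(params, swc, vpd, rg, ta = params$ta_opt) {
  b <- swc_capacity(swc, params) * vpd_multiplier(vpd, params) *
    ta_multiplier(ta, params)
  arg <- params$alpha_true * rg
  ifelse(rg > 0, arg * b / (arg + b), 0)
}

#' Analytic ground-truth sensitivities of GPP to SWC and VPD
#'
#' Analytic partial derivatives of the true GPP surface, converted to
#' standardized (z-score) units and reported in the drying orientation for
#' SWC (negative when drying reduces GPP) and increasing orientation for
#' VPD (negative when rising VPD reduces GPP).
#'
#' @param params A [truth_params()] object.
#' @param swc,vpd,rg,ta Evaluation points (vectors recycle).
#' @param sd_swc,sd_vpd,sd_gpp Standard deviations used to convert partials
#'   from natural units to z-units (defaults 1: raw partials).
#' @return data.frame with columns `s_swc` and `s_vpd`.
#' @export
true_sensitivities <- function(params, swc, vpd, rg, ta = params$ta_opt,
                               sd_swc = 1, sd_vpd = 1, sd_gpp = 1) {
  astar <- swc_capacity(swc, params) * ta_multiplier(ta, params)
  w <- ifelse(swc < params$swc_opt, params$swc_width, params$swc_width_hi)
  bump <- exp(-0.5 * ((swc - params$swc_opt) / w)^2)
  dastar <- params$amax_peak * ta_multiplier(ta, params) *
    (1 - params$swc_floor) * bump * (params$swc_opt - swc) / w^2
  m <- vpd_multiplier(vpd, params)
  dm <- ifelse(vpd > params$vpd0, -params$vpd_decay * m, 0)
  bb <- astar * m
  arg <- params$alpha_true * rg
  dgpp_db <- ifelse(rg > 0, arg^2 / (arg + bb)^2, 0)
  data.frame(
    s_swc = -dgpp_db * m * dastar * sd_swc / sd_gpp,
    s_vpd = dgpp_db * astar * dm * sd_vpd / sd_gpp
  )
}

#' Exact perturbation response of the true GPP surface
#'
#' The ground-truth value of the one-standard-deviation perturbation
#' statistic: the change in true GPP when one driver is shifted by a fixed
#' amount with the others held at their observed values, evaluated in
#' closed form. `d_swc` is applied as a negative (drying) shift and
#' `d_vpd` as a positive (moistening-deficit increase) shift, matching the
#' reporting orientations.
#'
#' @param params A [truth_params()] object.
#' @param swc,vpd,rg,ta Observed driver values.
#' @param d_swc SWC shift magnitude (%, applied as -d_swc).
#' @param d_vpd VPD shift magnitude (kPa, applied as +d_vpd).
#' @return data.frame with columns `s_swc`, `s_vpd` in umol m-2 s-1 per
#'   shift (divide by the response SD for z-units).
#' @export
true_perturbation <- function(params, swc, vpd, rg, ta, d_swc, d_vpd) {
  base <- gpp_true(params, swc, vpd, rg, ta)
  data.frame(
    s_swc = gpp_true(params, swc - d_swc, vpd, rg, ta) - base,
    s_vpd = gpp_true(params, swc, vpd + d_vpd, rg, ta) - base
  )
}

site_seed <- function(params, site_index) {
  as.integer((params$seed + 1009 * site_index) %% .Machine$integer.max)
}

#' Simulate meteorological drivers for one synthetic site
#'
#' Daily soil moisture follows a mean-reverting (AR1) anomaly process
#' around a seasonal sinusoid with precipitation-driven recharge and
#' year-to-year wetness offsets, clipped to 2-60%. Radiation is a seasonal
#' sinusoid with multiplicative weather noise, temperature is linear in
#' daily radiation, and relative humidity is constructed to rise with SWC
#' and fall with radiation so daily VPD correlates negatively with SWC.
#' Half-hourly downscaling uses a diurnal sine for radiation, temperature
#' and VPD; deeper SWC layers are lagged, smoothed copies of the surface
#' layer.
#'
#' @param params A [truth_params()] object.
#' @param site_index Site number (1-based); determines the sub-seed,
#'   plant functional type, canopy height and wetness offset.
#' @return A `site_series` list: `site_id`, `pft`, `zm`, `h_canopy`,
#'   `hh` (half-hourly driver table), `daily` (daily driver summary),
#'   `truth`.
#' @export
simulate_meteorology <- function(params, site_index = 1) {
  stopifnot(inherits(params, "truth_params"))
  set.seed(site_seed(params, site_index))
  nd <- params$n_days
  doy <- ((seq_len(nd) - 1) %% 365) + 1
  year <- 2001 + (seq_len(nd) - 1) %/% 365

  pfts <- c("ENF", "DBF", "GRA", "SAV")
  pft <- pfts[1 + (site_index - 1) %% length(pfts)]
  h_canopy <- switch(pft, ENF = stats::runif(1, 10, 22),
                     DBF = stats::runif(1, 12, 25),
                     GRA = stats::runif(1, 0.5, 1.5),
                     SAV = stats::runif(1, 3, 8))
  zm <- round(1.8 * h_canopy + 2, 1)
  site_wet <- stats::rnorm(1, 0, 2.5)
  # year-to-year wetness: mild wet years, occasional pronounced droughts
  ny <- length(unique(year))
  yo <- 1.5 - stats::rexp(ny, 1 / 6)
  year_off <- yo[match(year, unique(year))]

  # radiation: seasonal potential times an AR1 cloudiness factor
  rg_pot <- 180 + 170 * sin(2 * pi * (doy - 80) / 365)
  u <- stats::filter(stats::rnorm(nd, 0, 1.1), 0.6, method = "recursive")
  cloud <- 0.25 + 0.75 * stats::plogis(as.numeric(u) + 1)
  rg_d <- pmax(5, rg_pot * cloud)

  # radiation-linked plus independent synoptic (AR1) temperature variation
  synoptic <- as.numeric(stats::filter(stats::rnorm(nd, 0, 1.6), 0.7,
                                       method = "recursive"))
  ta_d <- 2 + 0.06 * rg_d + synoptic + stats::rnorm(nd, 0, 1)

  # persistent wet/dry regimes (2-state Markov chain) so drydowns produce
  # a realistic long dry tail in the SWC distribution
  wet <- logical(nd)
  wet[1] <- stats::runif(1) < 0.3
  u_markov <- stats::runif(nd)
  for (t in 2:nd)
    wet[t] <- u_markov[t] < (if (wet[t - 1]) 0.50 else 0.18)
  precip_d <- ifelse(wet, stats::rexp(nd, 1 / 7), 0)

  swc_seas <- 28 - 7 * sin(2 * pi * (doy - 100) / 365)
  # recharge from rain, drawdown on sunny days (evapotranspiration demand)
  innov <- 0.5 * (precip_d - mean(precip_d)) -
    0.004 * (rg_d - mean(rg_d)) + stats::rnorm(nd, 0, 1.0)
  anom <- as.numeric(stats::filter(innov, params$ar1_phi,
                                   method = "recursive"))
  swc_d <- pmin(60, pmax(2, swc_seas + site_wet + year_off + anom))

  rh_d <- pmin(0.98, pmax(0.15, 0.44 + 0.001 * swc_d -
                            0.0009 * (rg_d - 180) +
                            stats::rnorm(nd, 0, 0.10)))

  # deeper layers: moving-average smoothed, lagged copies of the surface
  smooth_lag <- function(x, k, lag) {
    s <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 1))
    s[is.na(s)] <- x[is.na(s)]
    c(rep(s[1], lag), s)[seq_along(x)]
  }
  swc2_d <- smooth_lag(swc_d, 5, 2)
  swc3_d <- smooth_lag(swc_d, 11, 5)
  swc4_d <- smooth_lag(swc_d, 21, 10)

  # half-hourly downscaling
  spd <- as.integer(24 * 60 / params$step_min)
  hod <- (seq_len(spd) - 1) * params$step_min / 60
  dshape <- pmax(0, sin(pi * (hod - 6) / 12))
  dshape_n <- dshape / mean(dshape)
  day_idx <- rep(seq_len(nd), each = spd)
  hod_all <- rep(hod, nd)

  rg <- rg_d[day_idx] * rep(dshape_n, nd)
  ta <- ta_d[day_idx] + 4 * cos(2 * pi * (hod_all - 14) / 24)
  vpd <- pmax(0.01, esat_kpa(ta) * (1 - rh_d[day_idx]))
  ws <- pmax(0.3, 1.2 + 1.3 * rep(dshape, nd) +
               stats::rlnorm(nd * spd, -0.3, 0.35))
  ratio <- 0.4 / log((zm - 0.67 * h_canopy) / (0.1 * h_canopy))
  ustar <- ws * ratio * exp(stats::rnorm(nd * spd, 0, 0.05))
  precip <- precip_d[day_idx] / spd

  t0 <- as.POSIXct("2001-01-01 00:00:00", tz = "UTC")
  timestamp <- t0 + (seq_len(nd * spd) - 1) * params$step_min * 60

  hh <- data.frame(
    timestamp = timestamp,
    date = as.Date(rep(seq(as.Date("2001-01-01"), by = 1,
                           length.out = nd), each = spd)),
    ta = ta, vpd = vpd, rg = rg,
    swc_1 = swc_d[day_idx], swc_2 = swc2_d[day_idx],
    swc_3 = swc3_d[day_idx], swc_4 = swc4_d[day_idx],
    ws = ws, ustar = ustar, precip = precip
  )
  daily <- data.frame(date = seq(as.Date("2001-01-01"), by = 1,
                                 length.out = nd),
                      year = year, rg = rg_d, ta = ta_d, swc = swc_d,
                      vpd = esat_kpa(ta_d) * (1 - rh_d),
                      precip = precip_d)
  structure(list(site_id = sprintf("SYN-%03d", site_index),
                 site_index = site_index, pft = pft,
                 zm = zm, h_canopy = h_canopy, hh = hh, daily = daily,
                 truth = params),
            class = "site_series")
}

#' @export
print.site_series <- function(x, ...) {
  cat(sprintf("Site %s (%s): zm = %.1f m, canopy %.1f m, %d half-hours\n",
              x$site_id, x$pft, x$zm, x$h_canopy, nrow(x$hh)))
  cat("  columns:", paste(names(x$hh), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate fluxes from drivers and the ground-truth response surface
#'
#' Adds to a driver series: true GPP (via the SWC/VPD-limited light
#' response), canopy conductance from a Medlyn-form stomatal model with a
#' soil-moisture downscaling below the stress threshold, latent heat from
#' the forward Penman-Monteith equation, Q10 respiration, NEE, noisy
#' night-time/daytime GPP realizations and quartile variants, energy-balance
#' columns and QC flags.
#'
#' @param met A `site_series` from [simulate_meteorology()].
#' @param params A [truth_params()] object (defaults to the one stored in
#'   `met`).
#' @return The `site_series` with flux columns appended to `$hh`.
#' @export
simulate_fluxes <- function(met, params = met$truth) {
  stopifnot(inherits(met, "site_series"))
  need <- c("ta", "vpd", "rg", "swc_1", "ws", "ustar")
  miss <- setdiff(need, names(met$hh))
  if (length(miss))
    stop("missing drivers in series: ", paste(miss, collapse = ", "))
  hh <- met$hh
  set.seed(site_seed(params, 500000L + met$site_index))
  n <- nrow(hh)
  nr <- params$noise_sd_rel

  gpp <- gpp_true(params, hh$swc_1, hh$vpd, hh$rg, hh$ta)
  fsoil <- stats::plogis((hh$swc_1 - (params$swc_lo - 5)) / 2)
  gc_mol <- params$g0 + 1.6 * (1 + params$g1 / sqrt(pmax(hh$vpd, 0.05))) *
    gpp / biophys_constants()$ca * fsoil
  gc_ms <- gc_mol / molar_density(hh$ta)

  rn <- 0.75 * hh$rg - 35
  g_soil <- 0.1 * rn
  ra <- aerodynamic_resistance(hh$ws, met$zm, met$h_canopy)
  le_true <- penman_monteith(gc_ms, ra, rn, g_soil, hh$ta, hh$vpd)

  reco <- params$reco_base * params$q10^((hh$ta - 15) / 10)
  nee_true <- reco - gpp

  rnois <- function() 1 + nr * stats::rnorm(n)
  hh$nee <- reco * rnois() - gpp * rnois()
  hh$gpp_nt <- gpp * rnois()
  hh$gpp_dt <- gpp * rnois()
  hh$gpp_nt_25 <- hh$gpp_nt * 0.85
  hh$gpp_nt_75 <- hh$gpp_nt * 1.15
  hh$le <- le_true * rnois()
  hh$le_corr <- (le_true / 0.88) * rnois()
  hh$h_flux <- rn - g_soil - le_true
  hh$rn <- rn
  hh$g_soil <- g_soil
  # exact (noise-free) process values kept for oracle checks
  hh$gpp_truth <- gpp
  hh$gc_mol_truth <- gc_mol
  hh$le_truth <- le_true
  hh$reco_truth <- reco
  hh$nee_truth <- nee_true
  hh$ra_truth <- ra

  qc_draw <- function() {
    u <- stats::runif(n)
    ifelse(u < params$qc_bad_frac, 2L, ifelse(u < params$qc_bad_frac + 0.1, 1L, 0L))
  }
  for (v in c("nee", "le", "ta", "vpd", "rg", "swc_1", "swc_2", "swc_3",
              "swc_4"))
    hh[[paste0("qc_", v)]] <- qc_draw()

  met$hh <- hh
  met
}

#' Simulate a complete site (drivers plus fluxes)
#' @inheritParams simulate_meteorology
#' @export
simulate_site <- function(params, site_index = 1) {
  simulate_fluxes(simulate_meteorology(params, site_index), params)
}

#' Simulate a network of synthetic sites
#' @param params A [truth_params()] object; `params$n_sites` sites are
#'   generated with reproducible per-site sub-seeds.
#' @return List of `site_series`.
#' @export
simulate_network <- function(params) {
  lapply(seq_len(params$n_sites), function(k) simulate_site(params, k))
}

#' Simulate a daily "model output" series (ESM-style)
#'
#' Produces the daily table an Earth-system-model extraction would give:
#' GPP, near-surface air temperature, downwelling shortwave, surface soil
#' moisture and VPD, at daily resolution only. GPP is computed from the
#' daily drivers through the same response-surface family, so a biased
#' model is emulated by passing different `params` (e.g. `vpd_decay = 0`
#' for a model without atmospheric-dryness limitation).
#'
#' @param params A [truth_params()] object governing the model's response.
#' @param site_index Site number; use the same index as the paired
#'   observational site so drivers are comparable.
#' @param met_params Optional [truth_params()] governing the drivers
#'   (defaults to `params`), allowing response and climate to differ.
#' @return data.frame with columns `date`, `gpp`, `tas`, `rsds`, `mrsos`,
#'   `vpd`.
#' @export
simulate_model_daily <- function(params, site_index = 1,
                                 met_params = params) {
  met <- simulate_meteorology(met_params, site_index)
  d <- met$daily
  rg_daytime <- 2 * d$rg   # daytime mean of the diurnal sine ~ twice the 24-h mean
  data.frame(date = d$date,
             gpp = gpp_true(params, d$swc, d$vpd, rg_daytime, d$ta),
             tas = d$ta, rsds = d$rg, mrsos = d$swc, vpd = d$vpd)
}
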