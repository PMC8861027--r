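# Orchestration: per-site biophysical derivation, preparation, the
# sensitivity-recovery study against the synthetic ground truth, the
# ESM-style model comparison, and the reproducible end-to-end demo run.

#' Derive canopy conductance, Amax, Vcmax and iWUE for one site
#'
#' Half-hourly canopy conductance from the Penman-Monteith inversion
#' (rainy days and the following day removed), daily Amax from
#' moving-window light-response fits of measured (non-gap-filled) CO2
#' flux, midday (11:00-14:00, Rg >= 500 W m-2) leaf-internal CO2, Vcmax
#' with 25 degC standardization, and iWUE = GPP/Gc. All outputs are
#' daytime daily values joined on date.
#'
#' @param site A `site_series` with flux columns.
#' @param le_variant "le" (default) or "le_corr" for the energy-balance
#'   corrected flux.
#' @param rain_mm Daily precipitation above which a day and its successor
#'   are excluded from the conductance inversion (default 0.1 mm).
#' @param ca Ambient CO2 mole fraction (umol mol-1).
#' @return data.frame per day: `date`, `gc_mol`, `amax`, `ci`, `vcmax`,
#'   `vcmax25`, `iwue`, `n_gc` (half-hours entering the Gc mean).
#' @export
derive_biophys <- function(site, le_variant = c("le", "le_corr"),
                           rain_mm = 0.1, ca = 400) {
  le_variant <- match.arg(le_variant)
  hh <- site$hh
  date <- hh$date %||% as.Date(hh$timestamp)
  hod <- as.numeric(format(hh$timestamp, "%H")) +
    as.numeric(format(hh$timestamp, "%M")) / 60

  h_can <- site$h_canopy
  if (is.na(h_can)) h_can <- site_canopy_height(hh$ws, hh$ustar, site$zm)
  ra <- aerodynamic_resistance(pmax(hh$ws, 0.1), site$zm, h_can)

  # rain filter: drop rainy days and the day after
  pday <- tapply(hh$precip, date, sum, na.rm = TRUE)
  rainy <- names(pday)[pday > rain_mm]
  rainy_next <- as.character(as.Date(rainy) + 1)
  dry <- !(as.character(date) %in% c(rainy, rainy_next))

  le <- hh[[le_variant]]
  ok_gc <- dry & qc_mask(hh, "le") & !is.na(le) & le > 0 & hh$vpd > 0 &
    hh$rg > 0
  gc_ms <- rep(NA_real_, nrow(hh))
  gc_ms[ok_gc] <- invert_penman_monteith(le[ok_gc], hh$rn[ok_gc],
                                         hh$g_soil[ok_gc], hh$ta[ok_gc],
                                         hh$vpd[ok_gc], ra[ok_gc])
  gc_mol <- gc_to_mol(gc_ms, hh$ta)

  day <- hod >= 7 & hod < 19
  dgc <- tapply(ifelse(day, gc_mol, NA_real_), date, mean, na.rm = TRUE)
  ngc <- tapply(day & !is.na(gc_mol), date, sum)

  # daily Amax from measured flux only
  fc <- ifelse(!is.na(hh$qc_nee) & hh$qc_nee == 0, hh$nee, NA_real_)
  lrc <- fit_light_response(date, fc, hh$rg, hh$vpd)

  # midday ci
  mid <- hod >= 11 & hod < 14 & hh$rg >= 500 & !is.na(gc_mol) & gc_mol > 0
  ra_mol <- ra / molar_density(hh$ta)
  ci_hh <- rep(NA_real_, nrow(hh))
  ci_hh[mid] <- leaf_internal_co2(hh$gpp_nt[mid], gc_mol[mid], ra_mol[mid],
                                  ca = ca, ta = hh$ta[mid])
  dci <- tapply(ci_hh, date, mean, na.rm = TRUE)
  dta_mid <- tapply(ifelse(mid, hh$ta, NA_real_), date, mean, na.rm = TRUE)

  dates <- sort(unique(date))
  key <- as.character(dates)
  out <- data.frame(date = dates,
                    gc_mol = as.numeric(dgc[key]),
                    n_gc = as.integer(ngc[key]),
                    ci = as.numeric(dci[key]),
                    ta_mid = as.numeric(dta_mid[key]))
  out$amax <- lrc$amax[match(dates, lrc$date)]
  vc <- invert_vcmax(out$amax, out$ci, out$ta_mid)
  out$vcmax <- vc$vcmax
  out$vcmax25 <- vc$vcmax25
  dgpp <- tapply(ifelse(day, hh$gpp_nt, NA_real_), date, mean, na.rm = TRUE)
  out$iwue <- iwue(as.numeric(dgpp[key]), out$gc_mol)
  for (v in c("gc_mol", "ci", "ta_mid", "vcmax", "vcmax25", "iwue"))
    out[[v]][is.nan(out[[v]])] <- NA_real_
  out
}

#' Prepare one site for sensitivity analysis
#'
#' Daytime daily aggregation, growing-season selection, z-scoring of the
#' analysis variables and 10 x 10 percentile binning.
#'
#' @param site A `site_series`.
#' @param layer SWC layer (1-4).
#' @param mode Growing-season mode (see [filter_growing_season()]).
#' @param responses Response columns to standardize alongside the drivers.
#' @param min_days Eligibility threshold in growing-season days.
#' @return List: `days_raw` (selected, natural units), `days` (standardized),
#'   `zparams`, `bins`, `eligible`, `n`.
#' @export
prep_site <- function(site, layer = 1, mode = "threshold",
                      responses = "gpp_nt", min_days = 300) {
  daily <- aggregate_daytime_daily(site, layer = layer)
  gs <- filter_growing_season(daily, mode = mode, min_days = min_days)
  sel <- gs$days
  sel <- sel[stats::complete.cases(sel[, c("ta", "vpd", "swc", "rg")]), ,
             drop = FALSE]
  vars <- unique(c(intersect(responses, names(sel)), "ta", "vpd", "swc",
                   "rg"))
  if (nrow(sel) < 10)
    return(list(days_raw = sel, days = NULL, zparams = NULL, bins = NULL,
                eligible = FALSE, n = nrow(sel)))
  z <- zscore(sel, vars)
  bins <- assign_bins(sel$swc, sel$vpd)
  list(days_raw = sel, days = z$days, zparams = z$params, bins = bins,
       eligible = gs$eligible, n = nrow(sel))
}

#' Daily ground-truth sensitivities for a synthetic site
#'
#' Daytime means of the half-hourly analytic partial derivatives of the
#' true GPP surface, in natural units (umol m-2 s-1 per % SWC and per kPa
#' VPD, already drying/increase oriented). Scale by sd_driver/sd_gpp of
#' the analysis set to obtain z-unit oracles.
#'
#' @param site A synthetic `site_series` (must carry `truth`).
#' @param method "derivative" for the analytic partials, "perturbation"
#'   for the exact finite one-SD perturbation response (the quantity the
#'   network estimator targets).
#' @param d_swc,d_vpd Shift magnitudes for `method = "perturbation"`
#'   (typically the analysis-set SDs of SWC and VPD).
#' @return data.frame: `date`, `s_swc`, `s_vpd`.
#' @export
daily_oracle <- function(site, method = c("derivative", "perturbation"),
                         d_swc = 1, d_vpd = 1) {
  method <- match.arg(method)
  if (is.null(site$truth)) stop("ground truth absent for this series")
  hh <- site$hh
  hod <- as.numeric(format(hh$timestamp, "%H")) +
    as.numeric(format(hh$timestamp, "%M")) / 60
  day <- hod >= 7 & hod < 19
  ts <- if (method == "derivative")
    true_sensitivities(site$truth, hh$swc_1, hh$vpd, hh$rg, hh$ta)
  else
    true_perturbation(site$truth, hh$swc_1, hh$vpd, hh$rg, hh$ta,
                      d_swc, d_vpd)
  d <- hh$date %||% as.Date(hh$timestamp)
  dates <- sort(unique(d))
  key <- as.character(dates)
  data.frame(
    date = dates,
    s_swc = as.numeric(tapply(ifelse(day, ts$s_swc, NA_real_), d, mean,
                              na.rm = TRUE)[key]),
    s_vpd = as.numeric(tapply(ifelse(day, ts$s_vpd, NA_real_), d, mean,
                              na.rm = TRUE)[key])
  )
}

#' Recover the ground-truth sensitivity pattern from a synthetic network
#'
#' End-to-end recovery study: simulates `params$n_sites` sites, prepares
#' each (threshold growing-season filter), trains the sensitivity networks,
#' aggregates per-site and cross-site grids, builds the matching oracle
#' grid from the analytic truth, and scores the error.
#'
#' @param params [truth_params()] for the study conditions.
#' @param spec [ann_spec()] for the networks.
#' @param base_seed Seed for the network seed policy.
#' @param response Response column.
#' @param min_days Cell occupancy for scoring (default 30).
#' @return List: `grid` (cross-site `sens_grid`), `oracle` (cross-site
#'   oracle matrices), `score_swc`, `score_vpd`
#'   (from [sensitivity_vs_truth()]), `sites` (per-site grids),
#'   `sign_stats`.
#' @export
recover_sensitivities <- function(params, spec = ann_spec(),
                                  base_seed = params$seed,
                                  response = "gpp_nt", min_days = 30) {
  site_grids <- vector("list", params$n_sites)
  oracle_swc <- vector("list", params$n_sites)
  oracle_vpd <- vector("list", params$n_sites)
  for (k in seq_len(params$n_sites)) {
    site <- simulate_site(params, k)
    prep <- prep_site(site, responses = response, min_days = 100)
    if (is.null(prep$days) || prep$n < 100) next
    site_grids[[k]] <- site_sensitivities(prep$days, prep$bins, response,
                                          spec, base_seed, k)
    zp <- prep$zparams
    orc <- daily_oracle(site, "perturbation", d_swc = zp$swc$sd,
                        d_vpd = zp$vpd$sd)
    m <- match(prep$days_raw$date, orc$date)
    oracle_swc[[k]] <- cell_median(orc$s_swc[m] / zp[[response]]$sd,
                                   prep$bins)
    oracle_vpd[[k]] <- cell_median(orc$s_vpd[m] / zp[[response]]$sd,
                                   prep$bins)
  }
  keep <- !vapply(site_grids, is.null, logical(1))
  grid <- cross_site_grid(site_grids[keep])
  med_over <- function(lst) {
    arr <- simplify2array(lst)
    if (length(dim(arr)) == 2) arr <- array(arr, c(10, 10, 1))
    apply(arr, c(1, 2), stats::median, na.rm = TRUE)
  }
  oracle <- list(swc = med_over(oracle_swc[keep]),
                 vpd = med_over(oracle_vpd[keep]))
  score_swc <- sensitivity_vs_truth(grid$swc$median, oracle$swc,
                                    grid$n_days, min_days)
  score_vpd <- sensitivity_vs_truth(grid$vpd$median, oracle$vpd,
                                    grid$n_days, min_days)

  pop <- grid$n_days >= min_days
  informative <- pop & !is.na(oracle$vpd) & abs(oracle$vpd) > 0.02
  sign_vpd <- mean(sign(grid$vpd$median[informative]) ==
                     sign(oracle$vpd[informative]))
  col_med <- function(m, rows) stats::median(m[rows, ][pop[rows, ]],
                                             na.rm = TRUE)
  sign_stats <- list(
    vpd_sign_agreement = sign_vpd,
    swc_wettest_decile = col_med(grid$swc$median, 10),
    swc_driest_two_deciles = col_med(grid$swc$median, 1:2)
  )
  list(grid = grid, oracle = oracle, score_swc = score_swc,
       score_vpd = score_vpd, sites = site_grids[keep],
       sign_stats = sign_stats)
}

#' Sensitivity analysis of a daily model-output series
#'
#' Applies the observational machinery to an ESM-style daily table (GPP
#' and drivers only, no biophysics stage): growing-season thresholds,
#' z-scores, percentile bins, networks, per-site grid.
#'
#' @param model_daily data.frame with columns `date`, `gpp`, `tas`,
#'   `rsds`, `mrsos`, `vpd` (see [simulate_model_daily()]).
#' @param spec [ann_spec()].
#' @param base_seed,site_index Seed policy inputs.
#' @return List: `grid` (a `site_grid`), `bins`, `days`, `warnings`.
#' @export
model_daily_sensitivities <- function(model_daily, spec = ann_spec(),
                                      base_seed = 42, site_index = 1) {
  need <- c("gpp", "tas", "rsds", "mrsos", "vpd")
  miss <- setdiff(need, names(model_daily))
  if (length(miss))
    stop("schema error: model series lacks column(s): ",
         paste(miss, collapse = ", "))
  warn <- character()
  if (nrow(model_daily) < 730)
    warn <- c(warn, "model series shorter than 2 years")
  d <- data.frame(date = model_daily$date, gpp_nt = model_daily$gpp,
                  ta = model_daily$tas, rg = model_daily$rsds,
                  swc = model_daily$mrsos, vpd = model_daily$vpd)
  # daily-mean radiation threshold scaled from the daytime-mean criterion
  sel <- d[!is.na(d$ta) & !is.na(d$vpd) & !is.na(d$rg) & d$ta > 15 &
             d$vpd > 0.5 & d$rg > 125, , drop = FALSE]
  sel <- sel[stats::complete.cases(sel), ]
  z <- zscore(sel, c("gpp_nt", "ta", "vpd", "swc", "rg"))
  bins <- assign_bins(sel$swc, sel$vpd)
  grid <- site_sensitivities(z$days, bins, "gpp_nt", spec, base_seed,
                             site_index)
  list(grid = grid, bins = bins, days = sel, warnings = warn)
}

#' Model-minus-observation sensitivity differences
#'
#' @param obs_grid Cross-site observational `sens_grid`.
#' @param model_grids List of per-site model `site_grid`s (one per paired
#'   site), aggregated with [cross_site_grid()] when more than one.
#' @return List: `d_swc`, `d_vpd` (model - observation, 10 x 10),
#'   `model_grid`.
#' @export
run_model_comparison <- function(obs_grid, model_grids) {
  mg <- if (inherits(model_grids, "site_grid")) model_grids
        else if (length(model_grids) == 1) model_grids[[1]]
        else cross_site_grid(model_grids, drop_excluded = FALSE)
  m_swc <- if (inherits(mg, "sens_grid")) mg$swc$median else mg$swc
  m_vpd <- if (inherits(mg, "sens_grid")) mg$vpd$median else mg$vpd
  list(d_swc = grid_difference(m_swc, obs_grid$swc$median),
       d_vpd = grid_difference(m_vpd, obs_grid$vpd$median),
       model_grid = mg)
}

#' Heatmap of a sensitivity grid
#'
#' @param grid 10 x 10 matrix (rows SWC decile, columns VPD decile).
#' @param main Plot title.
#' @export
plot_sensitivity_grid <- function(grid, main = "sensitivity") {
  pal <- grDevices::colorRampPalette(c("#b2182b", "white", "#2166ac"))(51)
  lim <- max(abs(grid), na.rm = TRUE)
  graphics::image(1:10, 1:10, t(grid), col = pal,
                  zlim = c(-lim, lim), xlab = "VPD decile",
                  ylab = "SWC decile", main = main)
  invisible(grid)
}
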