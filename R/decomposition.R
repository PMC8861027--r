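# Conditional decomposition of SWC versus VPD limitation: the change of
# the response between extreme driver deciles within each conditioning
# decile, with and without radiation normalization.

#' Normalize GPP by incoming shortwave radiation
#'
#' GPP_I = GPP / Rg per day, re-standardized to z-scores over the selected
#' day set, removing the first-order radiation effect from the response.
#'
#' @param days Daily table with unstandardized `rg` and the response.
#' @param response Response column (default "gpp_nt").
#' @return List: `days` (input with added standardized `gpp_i` column and
#'   rg <= 0 days dropped), `n_dropped`, `params` (z-score parameters).
#' @export
normalize_by_radiation <- function(days, response = "gpp_nt") {
  drop <- is.na(days$rg) | days$rg <= 0
  d <- days[!drop, , drop = FALSE]
  d$gpp_i <- d[[response]] / d$rg
  z <- zscore(d, "gpp_i")
  list(days = z$days, n_dropped = sum(drop), params = z$params)
}

#' Conditional extreme-decile response difference
#'
#' Within each conditioning decile, the mean response in the highest
#' populated decile of the driver minus the mean in the lowest populated
#' decile (deciles with fewer than `min_cell` days are not considered
#' populated). The site value averages the conditioning deciles where both
#' extremes are populated. For `driver = "swc"` the difference is oriented
#' low-minus-high SWC, so a water limitation is negative, matching the
#' orientation in which a VPD limitation (high minus low VPD) is negative.
#'
#' @param response Standardized response vector over the selected days.
#' @param bins `bin_grid` for those days.
#' @param driver "vpd" (conditioning on SWC deciles) or "swc"
#'   (conditioning on VPD deciles).
#' @param min_cell Minimum days per decile cell (default 3).
#' @return List of class `cond_delta`: `value` (site scalar), `per_bin`
#'   (vector over conditioning deciles), `driver`, `n_bins_used`.
#' @export
delta_conditional <- function(response, bins, driver = c("vpd", "swc"),
                              min_cell = 3) {
  driver <- match.arg(driver)
  if (driver == "vpd") { cond <- bins$i; drv <- bins$j }
  else { cond <- bins$j; drv <- bins$i }
  ok <- !is.na(response) & !is.na(cond) & !is.na(drv)
  response <- response[ok]; cond <- cond[ok]; drv <- drv[ok]
  per_bin <- rep(NA_real_, 10)
  for (c0 in 1:10) {
    sel <- cond == c0
    if (!any(sel)) next
    cnt <- table(factor(drv[sel], 1:10))
    pop <- which(cnt >= min_cell)
    if (length(pop) < 2) next
    lo <- min(pop); hi <- max(pop)
    d <- mean(response[sel & drv == hi]) - mean(response[sel & drv == lo])
    per_bin[c0] <- if (driver == "swc") -d else d
  }
  if (all(is.na(per_bin)))
    return(structure(list(value = NA_real_, per_bin = per_bin,
                          driver = driver, n_bins_used = 0,
                          note = "no conditioning decile with both extremes populated"),
                     class = "cond_delta"))
  structure(list(value = mean(per_bin, na.rm = TRUE), per_bin = per_bin,
                 driver = driver, n_bins_used = sum(!is.na(per_bin))),
            class = "cond_delta")
}

#' @export
print.cond_delta <- function(x, ...) {
  lab <- if (x$driver == "vpd") "dGPP(VPD|SWC)" else "dGPP(SWC|VPD)"
  cat(sprintf("%s = %.3f over %d conditioning deciles\n", lab, x$value,
              x$n_bins_used))
  invisible(x)
}

#' All four conditional deltas for one site
#'
#' Computes dGPP(VPD|SWC) and dGPP(SWC|VPD) for the raw standardized
#' response and for the radiation-normalized response GPP_I.
#'
#' @param days Daily table with unstandardized `rg` and the response, plus
#'   standardized columns used for binning already reflected in `bins`.
#' @param response_z Standardized response vector aligned with `days`.
#' @param bins `bin_grid` for the same days.
#' @param response Unstandardized response column name (for GPP_I).
#' @param min_cell Minimum cell occupancy.
#' @return data.frame with columns `term` and `value` (four rows).
#' @export
site_decomposition <- function(days, response_z, bins, response = "gpp_nt",
                               min_cell = 3) {
  d_vpd <- delta_conditional(response_z, bins, "vpd", min_cell)
  d_swc <- delta_conditional(response_z, bins, "swc", min_cell)
  keep <- !(is.na(days$rg) | days$rg <= 0)
  nr <- normalize_by_radiation(days, response)
  sub_bins <- list(i = bins$i[keep], j = bins$j[keep])
  di_vpd <- delta_conditional(nr$days$gpp_i, sub_bins, "vpd", min_cell)
  di_swc <- delta_conditional(nr$days$gpp_i, sub_bins, "swc", min_cell)
  data.frame(
    term = c("dGPP(VPD|SWC)", "dGPP(SWC|VPD)", "dGPP_I(VPD|SWC)",
             "dGPP_I(SWC|VPD)"),
    value = c(d_vpd$value, d_swc$value, di_vpd$value, di_swc$value)
  )
}
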