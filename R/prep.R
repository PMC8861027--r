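# Quality control, daytime aggregation, growing-season selection,
# z-scoring and percentile binning of flux-tower series.

#' Quality-control mask for one variable
#'
#' TRUE where the value is present and its QC twin is 0 (measured) or 1
#' (good gap-fill). GPP variants inherit the NEE QC flag they derive from.
#'
#' @param hh Half-hourly data.frame in internal names.
#' @param variable Variable name, e.g. "le", "gpp_nt", "swc_1".
#' @return Logical vector.
#' @export
qc_mask <- function(hh, variable) {
  qc_var <- if (grepl("^gpp", variable)) "qc_nee" else paste0("qc_", variable)
  if (!qc_var %in% names(hh))
    stop("QC twin column not found for '", variable, "' (", qc_var, ")")
  !is.na(hh[[variable]]) & !is.na(hh[[qc_var]]) & hh[[qc_var]] %in% c(0, 1)
}

#' Aggregate half-hourly records to daytime daily means
#'
#' Means over local hours in [7, 19) of timesteps passing the per-variable
#' QC mask; precipitation is summed over the full 24 h. Days with fewer
#' than `min_frac` valid daytime core records are flagged (`low_coverage`)
#' but retained.
#'
#' @param series A `site_series`.
#' @param layer SWC layer used as the analysis `swc` column (1-4).
#' @param day_start,day_end Daytime window in local hours, left-closed
#'   right-open.
#' @param min_frac Coverage threshold below which a day is flagged.
#' @return data.frame with one row per day: daytime means of GPP variants,
#'   drivers, energy terms, 24-h precip, `fraction_valid`, `low_coverage`.
#' @export
aggregate_daytime_daily <- function(series, layer = 1, day_start = 7,
                                    day_end = 19, min_frac = 0.5) {
  hh <- series$hh
  hod <- as.numeric(format(hh$timestamp, "%H")) +
    as.numeric(format(hh$timestamp, "%M")) / 60
  day <- hod >= day_start & hod < day_end
  date <- hh$date %||% as.Date(hh$timestamp)

  qc_or_true <- function(v) {
    qc_var <- if (grepl("^gpp", v)) "qc_nee" else paste0("qc_", v)
    if (qc_var %in% names(hh)) qc_mask(hh, v) else !is.na(hh[[v]])
  }
  mean_var <- function(v) {
    if (!v %in% names(hh)) return(NULL)
    ok <- day & qc_or_true(v)
    x <- ifelse(ok, hh[[v]], NA_real_)
    tapply(x, date, mean, na.rm = TRUE)
  }

  swc_var <- paste0("swc_", layer)
  vars <- intersect(c("gpp_nt", "gpp_dt", "gpp_nt_25", "gpp_nt_75", "ta",
                      "vpd", swc_var, "rg", "ws", "ustar", "le", "le_corr",
                      "rn", "g_soil"), names(hh))
  agg <- lapply(vars, mean_var)
  names(agg) <- vars
  dates <- sort(unique(date))
  out <- data.frame(date = dates)
  for (v in vars) {
    x <- agg[[v]][as.character(dates)]
    x[is.nan(x)] <- NA_real_
    out[[v]] <- as.numeric(x)
  }
  names(out)[names(out) == swc_var] <- "swc"

  if ("precip" %in% names(hh)) {
    p <- tapply(hh$precip, date, sum, na.rm = TRUE)
    out$precip <- as.numeric(p[as.character(dates)])
  }

  core <- intersect(c("gpp_nt", "ta", "vpd", swc_var, "rg"), names(hh))
  valid <- Reduce(`&`, lapply(core, qc_or_true))
  fv <- tapply(valid[day], date[day], mean)
  out$fraction_valid <- as.numeric(fv[as.character(dates)])
  out$fraction_valid[is.na(out$fraction_valid)] <- 0
  out$low_coverage <- out$fraction_valid < min_frac
  out$year <- as.integer(format(out$date, "%Y"))
  out
}

#' Select growing-season days
#'
#' `mode = "threshold"` keeps days with daily mean air temperature > 15
#' degC, VPD > 0.5 kPa and incoming shortwave radiation > 250 W m-2.
#' `mode = "peak3mo"` keeps the 3 consecutive calendar months (cyclic,
#' earliest window on ties) with maximum multi-year mean GPP.
#' `mode = "deseason"` applies the threshold selection and then returns
#' anomalies from the multi-year mean seasonal cycle smoothed with a 30-day
#' moving average.
#'
#' @param days Daily table from [aggregate_daytime_daily()].
#' @param mode One of "threshold", "peak3mo", "deseason".
#' @param min_days Eligibility rule: a site qualifies with at least this
#'   many selected days (default 300).
#' @return List: `days` (selected, possibly deseasonalized), `eligible`,
#'   `mode`, `n`.
#' @export
filter_growing_season <- function(days, mode = c("threshold", "peak3mo",
                                                 "deseason"),
                                  min_days = 300) {
  mode <- match.arg(mode)
  sel <- switch(mode,
    threshold = ,
    deseason = days[!is.na(days$ta) & !is.na(days$vpd) & !is.na(days$rg) &
                      days$ta > 15 & days$vpd > 0.5 & days$rg > 250, ,
                    drop = FALSE],
    peak3mo = {
      mo <- as.integer(format(days$date, "%m"))
      mgpp <- tapply(days$gpp_nt, mo, mean, na.rm = TRUE)
      mgpp_full <- rep(NA_real_, 12)
      mgpp_full[as.integer(names(mgpp))] <- mgpp
      win <- vapply(1:12, function(s) {
        mean(mgpp_full[((s - 1):(s + 1) %% 12) + 1])
      }, numeric(1))
      best <- which.max(win)   # ties: which.max returns the first
      keep_mo <- ((best - 1):(best + 1) %% 12) + 1
      days[mo %in% keep_mo, , drop = FALSE]
    })
  if (mode == "deseason" && nrow(sel) > 0) {
    doy <- as.integer(format(sel$date, "%j"))
    for (v in intersect(c("gpp_nt", "gpp_dt", "gpp_nt_25", "gpp_nt_75",
                          "ta", "vpd", "swc", "rg"), names(sel))) {
      clim <- rep(NA_real_, 366)
      m <- tapply(sel[[v]], doy, mean, na.rm = TRUE)
      clim[as.integer(names(m))] <- m
      # 30-day circular moving average over the day-of-year climatology
      sm <- vapply(1:366, function(d) {
        idx <- ((d - 15):(d + 14) - 1) %% 366 + 1
        mean(clim[idx], na.rm = TRUE)
      }, numeric(1))
      sel[[v]] <- sel[[v]] - sm[doy]
    }
  }
  list(days = sel, eligible = nrow(sel) >= min_days, mode = mode,
       n = nrow(sel))
}

#' Standardize variables to z-scores
#'
#' Each variable is centered on its mean and scaled by its sample standard
#' deviation (n-1 denominator) over the supplied day set. The returned
#' parameters allow exact inversion and re-application.
#'
#' @param days Daily table.
#' @param variables Character vector of columns to standardize.
#' @param params Optional stored parameters from a previous call; when
#'   given, they are applied instead of recomputed.
#' @return List: `days` (standardized), `params` (named list of
#'   mean/sd pairs).
#' @export
zscore <- function(days, variables, params = NULL) {
  if (is.null(params)) {
    params <- lapply(variables, function(v) {
      x <- days[[v]]
      if (sum(!is.na(x)) < 2 || length(unique(stats::na.omit(x))) < 2)
        stop("degenerate variable '", v, "': zero variance")
      s <- stats::sd(x, na.rm = TRUE)
      if (!is.finite(s) || s <= 0)
        stop("degenerate variable '", v, "': zero variance")
      list(mean = mean(x, na.rm = TRUE), sd = s)
    })
    names(params) <- variables
  }
  for (v in variables)
    days[[v]] <- (days[[v]] - params[[v]]$mean) / params[[v]]$sd
  list(days = days, params = params)
}

#' Invert a z-score transform
#' @param days Standardized daily table.
#' @param params Parameters from [zscore()].
#' @export
zscore_invert <- function(days, params) {
  for (v in names(params))
    days[[v]] <- days[[v]] * params[[v]]$sd + params[[v]]$mean
  days
}

#' Relative change of a summer mean versus the all-summer baseline
#'
#' 100 (x_year - x_ref) / x_ref, in percent.
#'
#' @param x_year Mean over one summer.
#' @param x_ref Mean over all summers (baseline), nonzero.
#' @export
relative_change <- function(x_year, x_ref) {
  if (any(x_ref == 0, na.rm = TRUE))
    stop("undefined baseline: reference mean is zero")
  100 * (x_year - x_ref) / x_ref
}

#' Assign days to 10 x 10 percentile bins of SWC and VPD
#'
#' Decile edges (10th, 20th, ..., 90th percentile; type-7 quantiles) are
#' computed per site from the selected days. Bins are left-closed and
#' right-open except the last, so a value equal to the 10th-percentile
#' edge falls in bin 2.
#'
#' @param swc,vpd Numeric vectors over the selected days.
#' @return List of class `bin_grid`: `edges_swc`, `edges_vpd` (length-9
#'   each), `i` (SWC decile 1-10), `j` (VPD decile 1-10).
#' @export
assign_bins <- function(swc, vpd) {
  ok <- !is.na(swc) & !is.na(vpd)
  if (sum(ok) < 10)
    stop("binning error: need at least 10 days with SWC and VPD present")
  probs <- seq(0.1, 0.9, by = 0.1)
  e_s <- stats::quantile(swc[ok], probs, type = 7, names = FALSE)
  e_v <- stats::quantile(vpd[ok], probs, type = 7, names = FALSE)
  i <- findInterval(swc, e_s) + 1L
  j <- findInterval(vpd, e_v) + 1L
  i[!ok] <- NA_integer_; j[!ok] <- NA_integer_
  structure(list(edges_swc = e_s, edges_vpd = e_v, i = i, j = j),
            class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat("10 x 10 percentile bin grid over", sum(!is.na(x$i)), "days\n")
  cat("  SWC decile edges:", paste(signif(x$edges_swc, 4), collapse = " "),
      "\n")
  cat("  VPD decile edges:", paste(signif(x$edges_vpd, 4), collapse = " "),
      "\n")
  invisible(x)
}
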