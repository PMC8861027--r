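# FLUXNET2015/ICOS CSV dialect: -9999 sentinel, TIMESTAMP_START in
# YYYYMMDDHHMM, unquoted fields. Internal (lower-case) column names map to
# the product's variable names below.

fluxnet_map <- function() {
  c(nee = "NEE_VUT_REF", gpp_nt = "GPP_NT_VUT_REF", gpp_dt = "GPP_DT_VUT_REF",
    gpp_nt_25 = "GPP_NT_VUT_25", gpp_nt_75 = "GPP_NT_VUT_75",
    le = "LE_F_MDS", le_corr = "LE_CORR", h_flux = "H_F_MDS",
    rn = "NETRAD", g_soil = "G_F_MDS", ta = "TA_F", vpd = "VPD_F",
    swc_1 = "SWC_F_MDS_1", swc_2 = "SWC_F_MDS_2", swc_3 = "SWC_F_MDS_3",
    swc_4 = "SWC_F_MDS_4", rg = "SW_IN_F", ws = "WS_F", ustar = "USTAR",
    precip = "P_F",
    qc_nee = "NEE_VUT_REF_QC", qc_le = "LE_F_MDS_QC", qc_ta = "TA_F_QC",
    qc_vpd = "VPD_F_QC", qc_rg = "SW_IN_F_QC",
    qc_swc_1 = "SWC_F_MDS_1_QC", qc_swc_2 = "SWC_F_MDS_2_QC",
    qc_swc_3 = "SWC_F_MDS_3_QC", qc_swc_4 = "SWC_F_MDS_4_QC")
}

#' Write a site series as a FLUXNET2015-dialect CSV
#'
#' Columns follow the FLUXNET2015 naming (TIMESTAMP_START/END, NEE_VUT_REF,
#' GPP_NT_VUT_REF, ...), missing values are written as -9999, fields are
#' unquoted. Numeric values are written with 17 significant digits so a
#' write/read cycle reproduces every finite double exactly.
#'
#' @param series A `site_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fluxnet_csv <- function(series, path) {
  hh <- series$hh
  step <- series$truth$step_min %||% {
    as.numeric(difftime(hh$timestamp[2], hh$timestamp[1], units = "mins"))
  }
  out <- data.frame(
    TIMESTAMP_START = format(hh$timestamp, "%Y%m%d%H%M"),
    TIMESTAMP_END = format(hh$timestamp + step * 60, "%Y%m%d%H%M"),
    stringsAsFactors = FALSE
  )
  map <- fluxnet_map()
  for (nm in names(map)) {
    if (!nm %in% names(hh)) next
    x <- hh[[nm]]
    s <- if (startsWith(nm, "qc_")) as.character(as.integer(x))
         else sprintf("%.17g", x)
    s[is.na(x)] <- "-9999"
    out[[map[[nm]]]] <- s
  }
  data.table::fwrite(out, path, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a FLUXNET2015-dialect flux CSV
#'
#' Parses TIMESTAMP_START, converts the -9999 sentinel to NA, renames the
#' product columns to the package's internal names, and records whether the
#' file is half-hourly or hourly (hourly files are flagged, never
#' interpolated).
#'
#' @param path CSV file path.
#' @param site_id,pft,zm Site metadata (id, plant functional type,
#'   measurement height in m).
#' @param layer Requested SWC layer (1-4); its column must be present.
#' @return A `site_series` with `$hh` in internal names.
#' @export
read_flux_csv <- function(path, site_id = basename(path), pft = NA_character_,
                          zm = NA_real_, layer = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, na.strings = c("-9999", "-9999.0", "NA"),
                          data.table = FALSE)
  map <- fluxnet_map()
  need <- c("TIMESTAMP_START", "NEE_VUT_REF", "GPP_NT_VUT_REF", "TA_F",
            "VPD_F", "SW_IN_F", sprintf("SWC_F_MDS_%d", layer))
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("schema error: missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  ts <- as.POSIXct(strptime(as.character(dt$TIMESTAMP_START), "%Y%m%d%H%M",
                            tz = "UTC"))
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1]
    stop("format error: unparseable timestamp at row ", bad, ": ",
         dt$TIMESTAMP_START[bad])
  }
  hh <- data.frame(timestamp = ts, date = as.Date(ts))
  for (nm in names(map)) if (map[[nm]] %in% names(dt)) hh[[nm]] <- dt[[map[[nm]]]]
  # belt-and-braces: any residual sentinel becomes NA
  for (nm in setdiff(names(hh), c("timestamp", "date")))
    hh[[nm]][!is.na(hh[[nm]]) & hh[[nm]] == -9999] <- NA
  step <- as.numeric(difftime(ts[2], ts[1], units = "mins"))
  structure(list(site_id = site_id, site_index = NA_integer_, pft = pft,
                 zm = zm, h_canopy = NA_real_, hh = hh, daily = NULL,
                 truth = NULL, hourly = isTRUE(step == 60)),
            class = "site_series")
}

#' Write a daily model-output series (ESM-style extraction) as CSV
#' @param daily data.frame from [simulate_model_daily()].
#' @param path Output file path.
#' @export
write_model_daily_csv <- function(daily, path) {
  out <- daily
  for (nm in setdiff(names(out), "date")) {
    s <- sprintf("%.17g", out[[nm]])
    s[is.na(out[[nm]])] <- "-9999"
    out[[nm]] <- s
  }
  data.table::fwrite(out, path, quote = FALSE)
  invisible(path)
}

#' Read a daily model-output series
#' @param path CSV with columns date, gpp, tas, rsds, mrsos, vpd.
#' @export
read_model_daily_csv <- function(path) {
  dt <- data.table::fread(path, na.strings = c("-9999", "NA"),
                          data.table = FALSE)
  need <- c("date", "gpp", "tas", "rsds", "mrsos", "vpd")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("schema error: missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  dt$date <- as.Date(dt$date)
  dt
}
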