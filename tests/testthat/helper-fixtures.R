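# Shared fixtures: small synthetic sites are expensive enough to cache
# per test run.

.fix_env <- new.env(parent = emptyenv())

tiny_params <- function(...) {
  truth_params(n_sites = 2, n_days = 120, ...)
}

cached_site <- function(key, params, site_index = 1) {
  if (is.null(.fix_env[[key]]))
    .fix_env[[key]] <- simulate_site(params, site_index)
  .fix_env[[key]]
}

# one noise-free site reused across biophysics/pipeline tests
noisefree_site <- function() {
  cached_site("noisefree",
              truth_params(n_sites = 1, n_days = 90, noise_sd_rel = 0,
                           qc_bad_frac = 0))
}

# a full-length default-parameter site for prep/decomposition tests
default_site <- function() {
  cached_site("default1", truth_params(n_sites = 4, n_days = 730), 1)
}

# a small hand-built half-hourly frame with controllable values
toy_halfhours <- function(n_days = 2, gpp = 10) {
  spd <- 48
  t0 <- as.POSIXct("2001-06-01 00:00:00", tz = "UTC")
  ts <- t0 + (seq_len(n_days * spd) - 1) * 1800
  hod <- as.numeric(format(ts, "%H")) + as.numeric(format(ts, "%M")) / 60
  data.frame(
    timestamp = ts, date = as.Date(ts),
    gpp_nt = ifelse(hod >= 7 & hod < 19, gpp, 0),
    ta = 20, vpd = 1.2, swc_1 = 25, rg = ifelse(hod >= 7 & hod < 19, 500, 0),
    precip = 0,
    qc_nee = 0L, qc_ta = 0L, qc_vpd = 0L, qc_rg = 0L, qc_swc_1 = 0L
  )
}
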