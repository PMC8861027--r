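# CSV dialect, QC masking, daytime aggregation, growing-season filters,
# z-scores, relative changes and percentile bins.

test_that("the FLUXNET CSV writer/reader round-trips every finite value", {
  s <- cached_site("io", truth_params(n_sites = 1, n_days = 30))
  path <- tempfile(fileext = ".csv")
  write_fluxnet_csv(s, path)
  r <- read_flux_csv(path, site_id = s$site_id, zm = s$zm)
  for (v in c("nee", "gpp_nt", "gpp_dt", "le", "le_corr", "ta", "vpd",
              "swc_1", "swc_4", "rg", "ws", "ustar"))
    expect_identical(r$hh[[v]], s$hh[[v]], label = v)
  expect_identical(r$hh$qc_nee, as.integer(s$hh$qc_nee))
  expect_equal(r$hh$timestamp, s$hh$timestamp)
})

test_that("the -9999 sentinel becomes a native missing value", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "TIMESTAMP_START,NEE_VUT_REF,GPP_NT_VUT_REF,TA_F,VPD_F,SW_IN_F,SWC_F_MDS_1",
    "200106010000,-9999,5.5,20,-9999,500,25",
    "200106010030,1.25,-9999,21,1.1,510,26"), path)
  r <- read_flux_csv(path)
  expect_true(is.na(r$hh$nee[1]))
  expect_true(is.na(r$hh$vpd[1]))
  expect_true(is.na(r$hh$gpp_nt[2]))
  expect_equal(r$hh$nee[2], 1.25)
})

test_that("schema and timestamp errors are specific", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("TIMESTAMP_START,NEE_VUT_REF,GPP_NT_VUT_REF,TA_F,VPD_F,SW_IN_F",
               "200106010000,1,2,3,4,5"), path)
  expect_error(read_flux_csv(path, layer = 1), "SWC_F_MDS_1")
  path2 <- tempfile(fileext = ".csv")
  writeLines(c(
    "TIMESTAMP_START,NEE_VUT_REF,GPP_NT_VUT_REF,TA_F,VPD_F,SW_IN_F,SWC_F_MDS_1",
    "notatime,1,2,3,4,5,6"), path2)
  expect_error(read_flux_csv(path2), "row 1")
  expect_error(read_flux_csv(tempfile()), "not found")
})

test_that("QC masking keeps flags 0-1 and drops missing values", {
  hh <- data.frame(le = c(1, 2, 3, 4, NA), qc_le = c(0, 1, 2, 3, 0))
  expect_equal(qc_mask(hh, "le"), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  hh$qc_le <- 0
  expect_equal(qc_mask(hh, "le"), c(rep(TRUE, 4), FALSE))
  expect_error(qc_mask(hh, "rg"), "QC twin")
  # GPP variants inherit the NEE flag
  hh2 <- data.frame(gpp_nt = 1:3, qc_nee = c(0, 2, 1))
  expect_equal(qc_mask(hh2, "gpp_nt"), c(TRUE, FALSE, TRUE))
})

test_that("daytime aggregation uses [07:00, 19:00) and excludes the night", {
  s <- list(hh = toy_halfhours(n_days = 2, gpp = 10))
  d <- aggregate_daytime_daily(s)
  expect_equal(nrow(d), 2)
  expect_equal(d$gpp_nt, c(10, 10))        # night zeros excluded
  expect_equal(d$fraction_valid, c(1, 1))  # 24 valid of 24 daytime slots
  expect_false(any(d$low_coverage))
})

test_that("QC-rejected half-hours are excluded from the daily mean", {
  hh <- toy_halfhours(n_days = 1, gpp = 10)
  hod <- as.numeric(format(hh$timestamp, "%H"))
  # poison the first 12 daytime half-hours with a flag >= 2 and value 999
  day_idx <- which(hod >= 7 & hod < 19)
  hh$gpp_nt[day_idx[1:12]] <- 999
  hh$qc_nee[day_idx[1:12]] <- 2L
  d <- aggregate_daytime_daily(list(hh = hh))
  expect_equal(d$gpp_nt, 10)
  expect_equal(d$fraction_valid, 0.5)
  expect_false(d$low_coverage)  # threshold is strict <
})

test_that("growing-season thresholds keep exactly the qualifying days", {
  days <- data.frame(
    date = as.Date("2001-06-01") + 0:4,
    ta = c(16, 14, 16, 16, 20), vpd = c(0.6, 0.6, 0.4, 0.6, 1.0),
    rg = c(300, 300, 300, 200, 400),
    gpp_nt = 5, year = 2001)
  gs <- filter_growing_season(days, "threshold", min_days = 300)
  expect_equal(nrow(gs$days), 2)
  expect_equal(gs$days$ta, c(16, 20))
  expect_false(gs$eligible)
  # all-fail edge
  days$ta <- 0
  gs2 <- filter_growing_season(days, "threshold")
  expect_equal(nrow(gs2$days), 0)
  expect_false(gs2$eligible)
  expect_error(filter_growing_season(days, "bogus"))
})

test_that("peak-3-month mode resolves ties to the earliest window", {
  days <- data.frame(date = seq(as.Date("2001-01-01"), as.Date("2002-12-31"),
                                by = 1))
  days$gpp_nt <- 5                      # constant across months: tie
  days$ta <- 20; days$vpd <- 1; days$rg <- 400
  days$year <- as.integer(format(days$date, "%Y"))
  gs <- filter_growing_season(days, "peak3mo")
  mo <- sort(unique(as.integer(format(gs$days$date, "%m"))))
  expect_equal(mo, c(1, 2, 3))  # earliest qualifying 3-month window
})

test_that("deseasonalized anomalies have no seasonal cycle left", {
  s <- default_site()
  daily <- aggregate_daytime_daily(s)
  gs <- filter_growing_season(daily, "deseason", min_days = 100)
  doy <- as.integer(format(gs$days$date, "%j"))
  # regressing anomalies on the annual harmonic finds (almost) nothing
  fit <- lm(gs$days$gpp_nt ~ sin(2 * pi * doy / 365) + cos(2 * pi * doy / 365))
  expect_lt(summary(fit)$r.squared, 0.05)
})

test_that("z-scores are exact, idempotent with stored parameters, invertible", {
  days <- data.frame(x = c(1, 2, 3))
  z <- zscore(days, "x")
  expect_equal(z$days$x, c(-1, 0, 1))            # n-1 denominator
  z2 <- zscore(z$days, "x")
  expect_lt(max(abs(z2$days$x - z$days$x)), 1e-12)
  back <- zscore_invert(z$days, z$params)
  expect_lt(max(abs(back$x - days$x)), 1e-12)
  expect_error(zscore(data.frame(x = rep(4, 5)), "x"), "degenerate")
})

test_that("relative change is a percent deviation from the baseline", {
  expect_equal(relative_change(75, 100), -25)
  expect_equal(relative_change(100, 100), 0)
  expect_equal(relative_change(122, 100), 22)
  expect_error(relative_change(1, 0), "baseline")
})

test_that("percentile bins partition days with the right boundary rule", {
  b <- assign_bins(1:100, 1:100)
  expect_equal(as.integer(table(b$i)), rep(10L, 10))
  # a value equal to the 10th-percentile edge lands in bin 2 (right-open)
  edge <- b$edges_swc[1]
  expect_equal(findInterval(edge, b$edges_swc) + 1L, 2L)
  expect_error(assign_bins(1:5, 1:5), "at least 10")
  # labels partition: counts sum to n
  set.seed(4)
  s <- runif(500); v <- runif(500)
  b2 <- assign_bins(s, v)
  expect_equal(sum(table(b2$i, b2$j)), 500)
})

test_that("independent uniform drivers fill cells to the binomial bound", {
  set.seed(8)
  b <- assign_bins(runif(10000), runif(10000))
  counts <- table(factor(b$i, 1:10), factor(b$j, 1:10))
  expect_true(all(counts >= 60 & counts <= 140))  # 100 +/- 40
})
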