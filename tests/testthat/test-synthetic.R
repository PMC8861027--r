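# Ground-truth generator: determinism, covariation, flux consistency,
# analytic sensitivities.

test_that("parameter validation names the offending field", {
  expect_error(truth_params(swc_lo = 40, swc_opt = 30), "swc_lo")
  expect_error(truth_params(vpd_decay = -1), "vpd_decay")
  expect_error(truth_params(amax_peak = 0), "amax_peak")
  expect_error(truth_params(ar1_phi = 1), "ar1_phi")
  expect_error(truth_params(noise_sd_rel = -0.1), "noise_sd_rel")
  expect_error(truth_params(n_days = 5), "n_days")
})

test_that("identical seeds give byte-identical series, sites differ", {
  p <- tiny_params(seed = 7)
  a <- simulate_site(p, 1)
  b <- simulate_site(p, 1)
  expect_identical(a$hh, b$hh)
  c <- simulate_site(p, 2)
  expect_false(identical(a$hh$swc_1, c$hh$swc_1))
})

test_that("soil-moisture memory is governed by the AR1 coefficient", {
  lag1 <- function(phi) {
    p <- truth_params(n_sites = 1, n_days = 1000, ar1_phi = phi, seed = 3)
    d <- simulate_meteorology(p, 1)$daily
    # remove the known deterministic parts (season, year level), keep the
    # stochastic anomaly whose memory the parameter controls
    doy <- as.integer(format(d$date, "%j"))
    fit <- lm(swc ~ sin(2 * pi * doy / 365) + cos(2 * pi * doy / 365) +
                factor(year), data = cbind(d, doy = doy))
    r <- resid(fit)
    cor(r[-1], r[-length(r)])
  }
  expect_lt(lag1(0), 0.3)      # only precipitation-regime memory remains
  expect_gt(lag1(0.9), 0.6)    # strong prescribed persistence
  expect_gt(lag1(0.9), lag1(0) + 0.3)
})

test_that("daily VPD and SWC covary negatively across a pooled network", {
  p <- truth_params(n_sites = 10, n_days = 365, seed = 11)
  pooled <- do.call(rbind, lapply(1:10, function(k)
    simulate_meteorology(p, k)$daily[, c("vpd", "swc")]))
  expect_lt(cor(pooled$vpd, pooled$swc), -0.3)
})

test_that("the stress-free limit collapses to the pure light response", {
  p <- truth_params(n_sites = 1, n_days = 60, noise_sd_rel = 0)
  met <- simulate_meteorology(p, 1)
  met$hh$vpd <- pmin(met$hh$vpd, p$vpd0)      # below decay onset
  met$hh$swc_1 <- p$swc_opt                    # at capacity optimum
  met$hh$ta <- p$ta_opt                        # at temperature optimum
  s <- simulate_fluxes(met, p)
  arg <- p$alpha_true * s$hh$rg
  expect_equal(s$hh$gpp_truth,
               ifelse(s$hh$rg > 0, arg * p$amax_peak / (arg + p$amax_peak), 0),
               tolerance = 1e-12)
})

test_that("respiration hits its base rate exactly at 15 degC", {
  p <- truth_params(n_sites = 1, n_days = 40, noise_sd_rel = 0)
  met <- simulate_meteorology(p, 1)
  met$hh$ta <- 15
  s <- simulate_fluxes(met, p)
  expect_equal(unique(s$hh$reco_truth), p$reco_base)
})

test_that("carbon closes exactly without noise: NEE + GPP - Reco = 0", {
  s <- noisefree_site()
  expect_lt(max(abs(s$hh$nee + s$hh$gpp_truth - s$hh$reco_truth)), 1e-10)
})

test_that("the forward Penman-Monteith fluxes invert back to the true conductance", {
  s <- noisefree_site()
  hh <- s$hh
  ok <- hh$rg > 0
  gc_ms_true <- hh$gc_mol_truth[ok] / molar_density(hh$ta[ok])
  rec <- invert_penman_monteith(hh$le_truth[ok], hh$rn[ok], hh$g_soil[ok],
                                hh$ta[ok], hh$vpd[ok], hh$ra_truth[ok])
  good <- !is.na(rec)
  expect_gt(mean(good), 0.95)
  expect_lt(max(abs(rec[good] - gc_ms_true[good]) / gc_ms_true[good]), 1e-8)
})

test_that("raising the VPD decay rate never raises true GPP", {
  p1 <- truth_params(vpd_decay = 0.2)
  p2 <- truth_params(vpd_decay = 0.8)
  set.seed(5)
  swc <- runif(200, 5, 50); vpd <- runif(200, 0.2, 4)
  rg <- runif(200, 50, 900); ta <- runif(200, 10, 30)
  expect_true(all(gpp_true(p2, swc, vpd, rg, ta) <=
                    gpp_true(p1, swc, vpd, rg, ta) + 1e-12))
})

test_that("analytic sensitivities honor their fixed points and match finite differences", {
  p <- truth_params()
  # below the decay onset the VPD partial vanishes
  expect_equal(true_sensitivities(p, 25, 0.8, 500, 20)$s_vpd, 0)
  # at the capacity optimum the SWC partial vanishes
  expect_equal(true_sensitivities(p, p$swc_opt, 1.5, 500, 20)$s_swc, 0)
  # below the stress threshold drying reduces GPP
  expect_lt(true_sensitivities(p, p$swc_lo - 2, 1.5, 500, 20)$s_swc, 0)
  # finite-difference agreement over random interior points
  set.seed(9)
  swc <- runif(50, 8, 45); vpd <- runif(50, 1.1, 3.5)
  rg <- runif(50, 100, 900); ta <- runif(50, 12, 30)
  ts <- true_sensitivities(p, swc, vpd, rg, ta)
  h <- 1e-6
  fd_swc <- -(gpp_true(p, swc + h, vpd, rg, ta) -
                gpp_true(p, swc - h, vpd, rg, ta)) / (2 * h)
  fd_vpd <- (gpp_true(p, swc, vpd + h, rg, ta) -
               gpp_true(p, swc, vpd - h, rg, ta)) / (2 * h)
  expect_lt(max(abs(ts$s_swc - fd_swc)), 1e-6)
  expect_lt(max(abs(ts$s_vpd - fd_vpd)), 1e-6)
})

test_that("the exact perturbation oracle matches direct surface evaluation", {
  p <- truth_params()
  tp <- true_perturbation(p, 20, 1.5, 500, 20, d_swc = 4, d_vpd = 0.5)
  expect_equal(tp$s_swc,
               gpp_true(p, 16, 1.5, 500, 20) - gpp_true(p, 20, 1.5, 500, 20))
  expect_equal(tp$s_vpd,
               gpp_true(p, 20, 2.0, 500, 20) - gpp_true(p, 20, 1.5, 500, 20))
})

test_that("flux simulation refuses driver-less input", {
  p <- tiny_params()
  met <- simulate_meteorology(p, 1)
  met$hh$swc_1 <- NULL
  expect_error(simulate_fluxes(met, p), "missing drivers")
})

test_that("the daily model-output series has the ESM extraction shape", {
  p <- truth_params(n_sites = 1, n_days = 400)
  md <- simulate_model_daily(p, 1)
  expect_named(md, c("date", "gpp", "tas", "rsds", "mrsos", "vpd"))
  expect_equal(nrow(md), 400)
  expect_true(all(md$gpp >= 0))
})
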