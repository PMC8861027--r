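# Network training, perturbation sensitivities, grid aggregation and
# significance testing.

make_xy <- function(n = 300, coefs = c(ta = 0.3, vpd = -0.45, swc = 0.22,
                                       rg = 0.5),
                    noise = 0, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, c("ta", "vpd", "swc", "rg")))
  y <- as.numeric(x %*% coefs) + noise * rnorm(n)
  list(x = x, y = y)
}

test_that("a noise-free linear response is learned almost perfectly", {
  d <- make_xy()
  fit <- train_ann(d$x, d$y, ann_spec(repeats = 1), seed = 3)
  expect_gt(fit$r_test, 0.999)
  expect_false(fit$excluded)
})

test_that("training is deterministic under a fixed seed", {
  d <- make_xy(noise = 0.3)
  f1 <- train_ann(d$x, d$y, seed = 42)
  f2 <- train_ann(d$x, d$y, seed = 42)
  expect_identical(f1$net$weights, f2$net$weights)
  expect_identical(predict(f1$net, d$x), predict(f2$net, d$x))
})

test_that("pure-noise responses trip the exclusion rule", {
  excluded <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    x <- matrix(rnorm(150 * 4), 150, 4,
                dimnames = list(NULL, c("ta", "vpd", "swc", "rg")))
    train_ann(x, rnorm(150), ann_spec(restarts = 1), seed = s)$excluded
  }, logical(1))
  expect_gte(mean(excluded), 0.9)
})

test_that("perturbation sensitivity collapses to coefficients for linear maps", {
  d <- make_xy(n = 400)
  fit <- train_ann(d$x, d$y, ann_spec(repeats = 1), seed = 7)
  s_vpd <- perturbation_sensitivity(fit, d$x, "vpd", delta = 1)
  expect_equal(median(s_vpd), -0.45, tolerance = 0.02)
  expect_lt(sd(s_vpd), 0.03)                    # same value every day
  # drying orientation: positive raw SWC coefficient reports negative
  s_swc <- perturbation_sensitivity(fit, d$x, "swc", delta = -1)
  expect_equal(median(s_swc), -0.22, tolerance = 0.02)
  # constant function has zero sensitivity
  const <- list(net = structure(list(weights = c(rep(0, 61)), hidden = 10,
                                     d = 4), class = "mlp"))
  class(const) <- "ann_fit"
  expect_equal(perturbation_sensitivity(const, d$x, "vpd"), rep(0, 400))
  expect_error(perturbation_sensitivity(fit, d$x, "humidity"), "unknown")
})

test_that("per-bin network sensitivities match the regression coefficients for linear truth", {
  set.seed(11)
  n <- 600
  swc_r <- rnorm(n); vpd_r <- -0.4 * swc_r + sqrt(1 - 0.16) * rnorm(n)
  x <- cbind(ta = rnorm(n), vpd = vpd_r, swc = swc_r, rg = rnorm(n))
  y <- 0.22 * swc_r - 0.45 * vpd_r + 0.3 * x[, "ta"] + 0.5 * x[, "rg"]
  days <- as.data.frame(x)
  days$gpp_nt <- y
  bins <- assign_bins(swc_r, vpd_r)
  g <- site_sensitivities(days, bins, "gpp_nt", ann_spec(repeats = 2),
                          base_seed = 1, site_index = 1)
  pop <- cell_count(bins) >= 3
  expect_lt(max(abs(g$swc[pop] - (-0.22)), na.rm = TRUE), 0.05)
  expect_lt(max(abs(g$vpd[pop] - (-0.45)), na.rm = TRUE), 0.05)
})

test_that("cell medians and repeat aggregation follow the median-of-medians rule", {
  bins <- list(i = c(1, 1, 1, 2), j = c(1, 1, 1, 5))
  m <- cell_median(c(0.1, 0.2, 0.9, 3), bins)
  expect_equal(m[1, 1], 0.2)
  expect_equal(m[2, 5], 3)
  expect_true(is.na(m[10, 10]))
  reps <- lapply(c(-0.5, -0.4, -0.45, -0.41, -0.44), function(v)
    matrix(v, 10, 10))
  expect_equal(bin_aggregate(reps)[3, 3], -0.44)
  # permuting repeat order changes nothing
  expect_identical(bin_aggregate(reps), bin_aggregate(rev(reps)))
  # empty cells stay missing
  expect_true(is.na(bin_aggregate(list(matrix(NA_real_, 10, 10)))[1, 1]))
})

test_that("cross-site aggregation degrades gracefully with few sites", {
  mk <- function(val) structure(list(swc = matrix(val, 10, 10),
                                     vpd = matrix(val, 10, 10),
                                     n_days = matrix(5L, 10, 10),
                                     excluded = FALSE, response = "gpp_nt"),
                                class = "site_grid")
  # 20 identical sites: zero SE, degenerate-certain significance
  g <- cross_site_grid(replicate(20, mk(-0.3), simplify = FALSE))
  expect_equal(g$swc$median[4, 4], -0.3)
  expect_equal(g$swc$se[4, 4], 0)
  expect_equal(g$swc$p[4, 4], 0)
  # single site: median but no SE or p-value
  g1 <- cross_site_grid(list(mk(-0.3)))
  expect_equal(g1$swc$median[2, 2], -0.3)
  expect_true(is.na(g1$swc$se[2, 2]))
  expect_true(is.na(g1$swc$p[2, 2]))
})

test_that("the cross-site t-test rejects near its nominal level under the null", {
  set.seed(13)
  rej <- replicate(1000, {
    vals <- rnorm(20, 0, 0.1)
    t.test(vals)$p.value < 0.05
  })
  expect_gt(mean(rej), 0.035)
  expect_lt(mean(rej), 0.065)
})

test_that("grid scoring against truth is an honest error map", {
  est <- matrix(rnorm(100), 10, 10)
  n <- matrix(50L, 10, 10)
  sc <- sensitivity_vs_truth(est, est, n)
  expect_equal(sc$error, matrix(0, 10, 10))
  expect_equal(sc$mae, 0)
  expect_equal(sc$n_cells, 100)
  expect_error(sensitivity_vs_truth(est, NULL, n), "truth absent")
  # cells below the occupancy floor are excluded from the MAE
  n2 <- n; n2[1, ] <- 10L
  expect_equal(sensitivity_vs_truth(est, est, n2)$n_cells, 90)
})

test_that("the LM network matches an independent nnet fit on a linear case", {
  skip_if_not_installed("nnet")
  d <- make_xy(n = 400, noise = 0.2, seed = 21)
  fit <- train_ann(d$x, d$y, ann_spec(repeats = 1), seed = 5)
  set.seed(5)
  ref <- nnet::nnet(d$x, d$y, size = 12, linout = TRUE, decay = 1e-4,
                    maxit = 1000, trace = FALSE)
  # both recover the same (true) linear map on held-out evaluation points
  set.seed(99)
  xe <- matrix(rnorm(200 * 4), 200, 4,
               dimnames = list(NULL, colnames(d$x)))
  truth <- as.numeric(xe %*% c(0.3, -0.45, 0.22, 0.5))
  expect_lt(sqrt(mean((predict(fit$net, xe) - truth)^2)), 0.1)
  expect_lt(sqrt(mean((as.numeric(predict(ref, xe)) - truth)^2)), 0.25)
})
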