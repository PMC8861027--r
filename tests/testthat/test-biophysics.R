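# Conductance, canopy geometry, Fick's-law ci and Farquhar inversions.

test_that("aerodynamic resistance matches the hand-evaluated log profile", {
  # h = 10 m, zm = 30 m, ws = 3: ra = ln(23.3/1)^2 / (3 * 0.16)
  expect_equal(aerodynamic_resistance(3, 30, 10),
               log(23.3 / 1)^2 / (3 * 0.16), tolerance = 1e-12)
  expect_equal(round(aerodynamic_resistance(3, 30, 10), 2), 20.65)
  # exact 1/ws proportionality
  expect_equal(aerodynamic_resistance(6, 30, 10),
               aerodynamic_resistance(3, 30, 10) / 2)
  # geometry singularity: zm at zd + z0
  expect_error(aerodynamic_resistance(3, 7.7, 10), "geometry")
  expect_error(aerodynamic_resistance(0, 30, 10), "positive")
})

test_that("canopy height follows the near-neutral wind-profile formula", {
  # ws -> 0 limit: h = zm / 0.7
  expect_equal(canopy_height(1e-12, 1, 30), 30 / 0.7, tolerance = 1e-9)
  # hand value: ws = 5, ustar = 0.5, zm = 30
  expect_equal(canopy_height(5, 0.5, 30), 30 / (0.6 + 0.1 * exp(4)),
               tolerance = 1e-12)
  expect_equal(round(canopy_height(5, 0.5, 30), 3), 4.951)
  # h scales linearly with zm at fixed ws/ustar
  expect_equal(canopy_height(5, 0.5, 60), 2 * canopy_height(5, 0.5, 30))
  expect_error(canopy_height(5, 0, 30), "ustar")
  # overflow guard
  expect_true(is.na(canopy_height(200, 1, 30)))
})

test_that("Penman-Monteith inversion closes the forward model", {
  set.seed(101)
  n <- 500
  gc <- runif(n, 0.001, 0.05)
  ra <- runif(n, 5, 80)
  rn <- runif(n, 100, 700)
  g <- 0.1 * rn
  ta <- runif(n, 5, 35)
  vpd <- runif(n, 0.2, 4)
  le <- penman_monteith(gc, ra, rn, g, ta, vpd)
  ok <- le > 0
  gc_rec <- invert_penman_monteith(le[ok], rn[ok], g[ok], ta[ok], vpd[ok],
                                   ra[ok])
  expect_gt(sum(ok), 400)
  expect_lt(max(abs(gc_rec - gc[ok]) / gc[ok]), 1e-10)
})

test_that("inverted conductance decreases monotonically with latent heat", {
  le <- seq(50, 400, by = 25)
  gc <- invert_penman_monteith(le, rn = 600, g_soil = 60, ta = 25,
                               vpd = 1.5, ra = 20)
  gc <- gc[!is.na(gc)]
  expect_true(all(diff(gc) > 0))  # more LE at fixed drivers needs more gc
  # halving le strictly decreases gc
  expect_lt(invert_penman_monteith(100, 600, 60, 25, 1.5, 20),
            invert_penman_monteith(200, 600, 60, 25, 1.5, 20))
})

test_that("degenerate inversions are flagged missing, not returned", {
  # LE at/above the aerodynamically unlimited rate implies infinite gc
  big_le <- penman_monteith(1e6, 20, 600, 60, 25, 1.5)
  expect_true(is.na(invert_penman_monteith(big_le * 1.01, 600, 60, 25,
                                           1.5, 20)))
  expect_true(is.na(invert_penman_monteith(100, 600, 60, 25, 0, 20)))
  expect_true(is.na(invert_penman_monteith(-5, 600, 60, 25, 1.5, 20)))
})

test_that("molar density honors the ideal gas law at the reference state", {
  expect_equal(molar_density(25, 101.325), 101325 / (8.314 * 298.15),
               tolerance = 1e-12)
  expect_equal(molar_density(25, 101.325), 40.87, tolerance = 3e-4)
  expect_equal(gc_to_mol(0.01, 25), 0.01 * molar_density(25))
})

test_that("leaf-internal CO2 follows Fick's law with sane guards", {
  # hand value: ca 400, gpp 20, gc 0.4 mol, ra_mol ~ 0
  expect_equal(leaf_internal_co2(20, 0.4, 0), 320)
  # no drawdown without assimilation
  expect_equal(leaf_internal_co2(0, 0.4, 0), 400)
  # infinite conductance limit
  expect_equal(leaf_internal_co2(20, 1e9, 0), 400, tolerance = 1e-6)
  expect_true(is.na(leaf_internal_co2(20, 0, 0)))
  # below the compensation point is physically invalid
  expect_true(is.na(leaf_internal_co2(120, 0.4, 0)))
})

test_that("Vcmax inversion reproduces the pinned-kinetics hand value", {
  k25 <- 404.9 * (1 + 210 / 278.4)
  expect_equal(michaelis_k(25), k25, tolerance = 1e-12)
  v <- invert_vcmax(20, 320, 25)
  expect_equal(v$vcmax, 20 * (320 + k25) / (320 - 42.75), tolerance = 1e-12)
  expect_equal(v$vcmax, 74.33, tolerance = 1e-4)
  # Arrhenius identity at the 25 degC reference
  expect_equal(v$vcmax25, v$vcmax)
  expect_equal(invert_vcmax(0, 320, 25)$vcmax, 0)
  # ci at or below the compensation point is flagged
  expect_true(is.na(invert_vcmax(20, 40, 25)$vcmax))
})

test_that("Farquhar forward/inverse closure holds over a parameter grid", {
  grid <- expand.grid(vcmax = c(20, 60, 120), ci = c(150, 250, 350),
                      ta = c(10, 25, 35))
  am <- forward_amax(grid$vcmax, grid$ci, grid$ta)
  rec <- invert_vcmax(am, grid$ci, grid$ta)
  expect_lt(max(abs(rec$vcmax - grid$vcmax)), 1e-10)
})

test_that("iWUE is the GPP/Gc ratio with guards and homogeneity", {
  expect_equal(iwue(20, 0.4), 50)
  expect_equal(iwue(0, 0.4), 0)
  expect_equal(iwue(40, 0.8), iwue(20, 0.4))
  expect_true(is.na(iwue(20, 0)))
})
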