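test_that("PDE degradation matches independent hand evaluation", {
  p <- signaling_params()
  camp <- 0.1
  by_hand <- 20 * 4.5 * camp / (50 + camp) +
    1.25 * 5.6 * camp / (0.08 + camp) +
    2.5 * 2.0 * camp / (2.2 + camp)
  expect_equal(pde_degradation_rate(p, camp), by_hand)
  expect_equal(by_hand, 4.2859, tolerance = 1e-4)
  expect_identical(pde_degradation_rate(p, 0), 0)
  # linear in the PDE concentrations
  expect_equal(pde_degradation_rate(p, 0.37, pde_scale = 10),
               10 * pde_degradation_rate(p, 0.37))
})

test_that("AC production has the basal offset, monotonicity and ATP saturation", {
  p <- signaling_params()
  # with no active Gs-alpha-GTP only the basal factor 0.7 remains
  p_inf_atp <- signaling_params(atp = 1e12)
  basal_factor <- ac_production_rate(p_inf_atp, 0, ac_scale = 1) /
    (p$mw_ac / 60e-3 * p$ac / p$af)
  expect_equal(basal_factor, 0.7, tolerance = 1e-9)
  # strictly increasing in Gs-alpha-GTP
  g <- seq(0, 5, length.out = 50)
  rates <- ac_production_rate(p, g)
  expect_true(all(diff(rates) > 0))
  # ATP saturation approaches 1 from below
  expect_lt(ac_production_rate(p, 1), ac_production_rate(p_inf_atp, 1))
  expect_error(ac_production_rate(p, -0.1), ">= 0")
})

test_that("calibrated AC scale balances basal production and degradation", {
  p <- signaling_params()
  s <- calibrate_ac_scale(p)
  expect_equal(ac_production_rate(p, gprotein_state()$gsa_gtp, s),
               pde_degradation_rate(p, 0.1))
})

test_that("receptor algebra: no ligand collapses to the receptor-Gs equilibrium", {
  p <- signaling_params()
  st <- gprotein_state()
  alg <- solve_receptor_algebra(p, st, liso = 0)
  expect_identical(alg$lrb1, 0)
  expect_identical(alg$lrgs, 0)
  # closed form: RGS = RT q / (1 + q) with q = gs_free/(gs_free + KC)
  gs_free <- p$gs_total - st$gsa_gtp - st$gsa_gdp
  q <- gs_free / (gs_free + p$k_c)
  expect_equal(alg$rgs, p$rb1_total * q / (1 + q), tolerance = 1e-10)
  # zero receptor pool
  p0 <- signaling_params(rb1_total = 0)
  alg0 <- solve_receptor_algebra(p0, st)
  expect_identical(unlist(alg0[c("rb1_free", "rgs", "lrb1", "lrgs")]),
                   c(rb1_free = 0, rgs = 0, lrb1 = 0, lrgs = 0))
})

test_that("receptor algebra agrees with a brute-force grid search", {
  p <- signaling_params()
  st <- gprotein_state()
  alg <- solve_receptor_algebra(p, st, liso = 30)
  # independent oracle: dense scan of the conservation residual in rb1_free
  gs_free <- p$gs_total - st$gsa_gtp - st$gsa_gdp
  resid <- function(rf) {
    rgs <- rf * gs_free / (gs_free + p$k_c)
    l <- 30e-3
    lrb1 <- l * (rf - rgs) / (l + p$k_l)
    lrgs <- lrb1 * (gs_free - rgs) /
      ((gs_free - rgs) + p$k_c * p$k_h / p$k_l) +
      l * rgs / (l + p$k_h)
    rf + lrb1 + lrgs + rgs - p$rb1_total
  }
  grid <- seq(0, p$rb1_total, length.out = 200001)
  best <- grid[which.min(abs(vapply(grid, resid, numeric(1))))]
  expect_equal(alg$rb1_free, best, tolerance = 1e-4)
  # conservation holds to solver tolerance
  expect_equal(alg$rb1_free + alg$lrb1 + alg$lrgs + alg$rgs, p$rb1_total,
               tolerance = 1e-10)
  expect_lt(abs(alg$residual), 1e-10)
})

test_that("G-protein step: pure hydrolysis decays exponentially, dt -> 0 is identity", {
  p <- signaling_params(kact1 = 0, kact2 = 0, kreas = 0)
  st <- gprotein_state(gsa_gtp = 1, gsa_gdp = 0, gs_bg = 0.042)
  dt <- 1e-4
  x <- st
  for (i in 1:1000) x <- step_gprotein(x, p, dt, liso = 0)
  expect_equal(x$gsa_gtp, exp(-p$khydr * 0.1), tolerance = 1e-3)
  tiny <- step_gprotein(st, p, 1e-12, liso = 0)
  expect_equal(tiny$gsa_gtp, st$gsa_gtp, tolerance = 1e-9)
})

test_that("G-protein dynamics reach the activation/hydrolysis balance", {
  p <- signaling_params()
  st <- gprotein_state()
  dt <- 1e-3
  for (i in 1:6000) st <- step_gprotein(st, p, dt)
  alg <- solve_receptor_algebra(p, st)
  act <- alg$lrgs * p$kact2 + alg$rgs * p$kact1
  expect_equal(act, st$gsa_gtp * p$khydr, tolerance = 1e-2)
  expect_true(all(unlist(st) >= 0))
})
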