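test_that("geometry carries 100 exact caveolar domains at 0.5% area fraction", {
  g <- sarcomere_geometry()
  # 50 caveolae per membrane edge, each 0.1 um long x 0.01 um deep, resolved
  # by 2 z-cells x 1 fine x-cell
  expect_equal(sum(g$cav), 2 * 50 * 2)
  expect_equal(sum(g$area[g$cav]) / sum(g$area), 0.005, tolerance = 1e-12)
  expect_true(!any(g$cav & g$ecav))
  expect_equal(sum(g$area), 20)
  # caveolae-free geometry is pure diffusion
  g0 <- sarcomere_geometry(n_caveolae = 0)
  expect_equal(sum(g0$cav), 0)
  expect_error(sarcomere_geometry(dz = 0.03), "divide")
  expect_error(sarcomere_geometry(n_caveolae = 7), "tile")
})

test_that("implicit diffusion leaves a uniform field unchanged and conserves mass", {
  g <- small_geometry()
  for (method in c("backward", "adi")) {
    work <- sarcomere_stepper(g, d = 300, dt = 1e-3, method = method)
    u <- matrix(0.7, g$nx, g$nz)
    u1 <- step_diffusion_implicit(u, g, 300, 1e-3, work = work)
    expect_equal(u1, u, tolerance = 1e-12)
    set.seed(7)
    f <- matrix(runif(g$nx * g$nz), g$nx, g$nz)
    m0 <- sum(f * g$area)
    for (i in 1:20) f <- step_diffusion_implicit(f, g, 300, 1e-3, work = work)
    expect_equal(sum(f * g$area), m0, tolerance = 1e-10)
    expect_true(all(is.finite(f)))
  }
})

test_that("a point pulse spreads with variance ~ 2 D t before boundaries matter", {
  g <- sarcomere_geometry(n_caveolae = 0)
  d <- 60; dt <- 1e-5
  f <- matrix(0, g$nx, g$nz)
  ic <- which.min(abs(g$xc - 1)); jc <- which.min(abs(g$zc - 5))
  f[ic, jc] <- 1 / g$area[ic, jc]
  work <- sarcomere_stepper(g, d, dt)
  nstep <- 30
  for (i in seq_len(nstep)) f <- step_diffusion_implicit(f, g, d, dt, work = work)
  w <- f * g$area / sum(f * g$area)
  vz <- sum(w * outer(rep(1, g$nx), (g$zc - 5)^2))
  # backward Euler adds one step's worth of spread; compare to 2 D t (n+1)
  expect_equal(vz, 2 * d * dt * (nstep + 1), tolerance = 0.05)
})

test_that("reaction mass balance: field change equals dt * net reaction", {
  g <- small_geometry()
  p <- signaling_params()
  f <- matrix(0.1, g$nx, g$nz)
  reaction <- matrix(0, g$nx, g$nz)
  reaction[g$cav] <- 5 - pde_degradation_rate(p, f[g$cav], 10)
  m0 <- sum(f * g$area)
  f1 <- step_diffusion_implicit(f, g, 10, 1e-3, reaction = reaction)
  dm <- sum(f1 * g$area) - m0
  expect_equal(dm, 1e-3 * sum(reaction * g$area), tolerance = 1e-6)
})

test_that("symmetric initial conditions stay mirror-symmetric", {
  res <- simulate_sarcomere(d = 60, pde_scale = 10, duration = 0.2)
  f <- res$field
  expect_lt(max(abs(f - f[, rev(seq_len(ncol(f)))])), 1e-9)  # z mirror
  expect_lt(max(abs(f - f[rev(seq_len(nrow(f))), ])), 1e-9)  # x mirror
  expect_true(all(f >= 0))
})

test_that("ADI converges to the backward-Euler solution as dt shrinks", {
  # without the thin reactive layer the two schemes are interchangeable
  g <- small_geometry()
  f0 <- 0.1 + 0.01 * outer(cos(pi * g$xc / g$width),
                           cos(pi * g$zc / g$length))
  fa <- f0; fb <- f0
  wa <- sarcomere_stepper(g, 60, 1e-3, "adi")
  wb <- sarcomere_stepper(g, 60, 1e-3, "backward")
  for (i in 1:50) {
    fa <- step_diffusion_implicit(fa, g, 60, 1e-3, work = wa)
    fb <- step_diffusion_implicit(fb, g, 60, 1e-3, work = wb)
  }
  expect_equal(fa, fb, tolerance = 1e-4)
  # with the stiff caveolar reaction layer the ADI splitting error in the
  # caveolar mean decays ~ dt^2 towards the backward-Euler trajectory
  err <- vapply(c(1e-3, 2e-4), function(dt) {
    a <- simulate_sarcomere(d = 300, pde_scale = 1, duration = 0.2, dt = dt,
                            method = "adi")
    b <- simulate_sarcomere(d = 300, pde_scale = 1, duration = 0.2, dt = dt,
                            method = "backward")
    abs(a$series$mean_cav[nrow(a$series)] - b$series$mean_cav[nrow(b$series)])
  }, numeric(1))
  expect_lt(err[2], err[1] / 5)
  expect_lt(err[2], 0.01)
})

test_that("gradient classifier applies the 15% production-site rule", {
  g <- small_geometry()
  uni <- matrix(0.5, g$nx, g$nz)
  c1 <- classify_gradient(uni, g)
  expect_identical(c1$classification, "none")
  expect_false(c1$pka_relevant)
  # 20% drop away from the caveolar production site
  f <- matrix(0.8, g$nx, g$nz)
  f[g$cav] <- 1
  f[round(g$nx / 2), ] <- 0.8
  # production-site mean is 1.0; minimum 0.8 -> 20% drop
  c2 <- classify_gradient(f, g)
  expect_identical(c2$classification, "significant")
  expect_equal(c2$drop, 0.2, tolerance = 1e-12)
  expect_false(classify_gradient(matrix(0.99, g$nx, g$nz), g)$pka_relevant)
  expect_true(classify_gradient(matrix(1.01, g$nx, g$nz), g)$pka_relevant)
})

test_that("gradient metrics converge under grid refinement", {
  coarse <- simulate_sarcomere(d = 10, pde_scale = 10, duration = 0.25,
                               snapshot_times = 0.25)
  fine <- simulate_sarcomere(d = 10, pde_scale = 10, duration = 0.25,
                             geometry = sarcomere_geometry(
                               dz = 0.025, dx_fine = 0.005,
                               dx_coarse = 0.025),
                             snapshot_times = 0.25)
  gc_ <- classify_gradient(coarse$snapshots[[1]], coarse$geometry)
  gf <- classify_gradient(fine$snapshots[[1]], fine$geometry)
  expect_equal(gc_$gradient, gf$gradient, tolerance = 0.05)
})

test_that("washout reports equilibration and decline landmarks", {
  w <- run_scenario_washout(d = 300, max_duration = 0.02)
  # fast diffusion equilibrates the caveolar space within one 1 ms step
  expect_equal(w$equilibration_time, 0.001)
  expect_gt(w$cav_first_step, 0.95)
  expect_lte(w$cav_first_step, 1.0 + 1e-9)
})
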