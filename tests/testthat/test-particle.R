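test_that("binding calibration scales as sqrt(dt) and respects the cap", {
  k <- kinetic_constants()
  p1 <- calibrate_binding(k, sigma = 2500, dt = 1e-6, d = 300)
  p4 <- calibrate_binding(k, sigma = 2500, dt = 4e-6, d = 300)
  expect_equal(p4 / p1, 2, tolerance = 1e-12)
  # published operating point: dt = 5e-9 s admissible (p < 1) even at the
  # densest surface grid
  for (n in 10^(1:5)) {
    s <- surface_grid_density(n)
    expect_lt(calibrate_binding(k, s, 5e-9, 300), 1)
    expect_gte(admissible_dt(k, s, 300, cap = 1), 5e-9)
  }
  # monotonicity: denser grids demand smaller steps, faster diffusion larger
  expect_lt(admissible_dt(k, 25000, 300), admissible_dt(k, 2500, 300))
  expect_gt(admissible_dt(k, 2500, 300), admissible_dt(k, 2500, 10))
  expect_error(particle_scenario(d = 300, n_pde = 1e5, dt = 1e-4),
               "inadmissible")
})

test_that("surface grid density follows the published table", {
  expect_identical(surface_grid_density(10), 1500)
  expect_identical(surface_grid_density(1000), 25000)
  expect_identical(surface_grid_density(1e5), 2.5e6)
  # off-table counts pack one site per cell
  expect_equal(surface_grid_density(50), 50 / 0.04)
})

test_that("particle bookkeeping is exact and walls conserve particles", {
  set.seed(11)
  sc <- particle_scenario(d = 300, n_pde = 100, dt = 1e-6, duration = 0.05,
                          frame_interval = 5e-3)
  run <- run_particle(sc)
  expect_identical(run$produced,
                   run$degraded + run$free_count + run$bound_count)
  # no sinks, no source: count constant over every frame
  set.seed(12)
  sc0 <- particle_scenario(d = 300, n_pde = 0, dt = 1e-6, duration = 0.05,
                           source_rate = 0, init_n = 250)
  run0 <- run_particle(sc0)
  expect_true(all(run0$frame_count == 250))
  expect_identical(run0$degraded, 0)
})

test_that("source-only runs accumulate at the emission rate", {
  set.seed(13)
  sc <- particle_scenario(d = 300, n_pde = 0, dt = 1e-6, duration = 0.5)
  run <- run_particle(sc)
  # Poisson(120 * 0.5): within 4 sd
  expect_lt(abs(run$produced - 60), 4 * sqrt(60))
  expect_identical(run$free_count, run$produced)
})

test_that("stationary distribution of a sealed box is uniform in z", {
  set.seed(14)
  sc <- particle_scenario(d = 300, n_pde = 0, dt = 1e-6, duration = 0.05,
                          source_rate = 0, init_n = 400, nbins = 10L,
                          frame_interval = 0.05)
  run <- run_particle(sc)
  counts <- as.numeric(run$frames[nrow(run$frames), ])
  expect_gt(stats::chisq.test(counts)$p.value, 1e-3)
})

test_that("well-mixed box recovers the macroscopic association rate within 5%", {
  set.seed(1)
  sc <- particle_scenario(d = 300, n_pde = 100, dt = 1e-6)
  v <- validate_binding_rate(sc, n_particles = 2000, duration = 0.05)
  expect_equal(v$ratio, 1, tolerance = 0.05)
})

test_that("profile fitter recovers its own model class exactly", {
  sc <- particle_scenario(d = 10, n_pde = 1000, dt = 1e-6)
  sol <- solve_steady_state(barrier_scenario(
    d = 10, pde_tot = pde_count_to_concentration(1000)))
  mids <- (seq_len(sc$nbins) - 0.5) / sc$nbins * sc$box[3]
  conc <- ifelse(mids <= sc$l_star,
                 (sol$a + sol$b) - sol$a / sc$l_star * mids, sol$b)
  prof <- synthetic_profile(conc, sc)
  est <- estimate_r(prof, n_boot = 20)
  expect_equal(est$r, sol$r, tolerance = 1e-6)
  expect_false(est$flagged)
  # flat profile: no compartmentation
  est0 <- estimate_r(synthetic_profile(rep(0.5, sc$nbins), sc), n_boot = 20)
  expect_equal(est0$r, 0, tolerance = 1e-9)
})

test_that("runs are reproducible bit-for-bit under a fixed seed", {
  sc <- particle_scenario(d = 10, n_pde = 100, dt = 1e-6, duration = 0.02,
                          frame_interval = 1e-3)
  set.seed(99); a <- run_particle(sc)
  set.seed(99); b <- run_particle(sc)
  expect_identical(a$frames, b$frames)
  expect_identical(a$produced, b$produced)
})

test_that("z profile demands frames and bins around the barrier", {
  set.seed(5)
  sc <- particle_scenario(d = 300, n_pde = 0, dt = 1e-6, duration = 0.02,
                          frame_interval = 1e-3)
  run <- run_particle(sc)
  expect_error(z_profile(run, window = c(5, 6)), "no frames")
  prof <- z_profile(run, window = c(0, Inf))
  expect_s3_class(prof, "z_profile")
  expect_equal(nrow(prof), sc$nbins)
})
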