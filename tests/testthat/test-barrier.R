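test_that("steady-state solution satisfies the flux-balance identity", {
  # at steady state the barrier hydrolyses exactly the injected flux:
  # kcat * (pde_tot * l_star) * B/(Km+B) = j_b
  grid <- expand.grid(d = c(300, 60, 10),
                      pde = pde_count_to_concentration(10^(1:5)))
  for (i in seq_len(nrow(grid))) {
    sc <- barrier_scenario(d = grid$d[i], pde_tot = grid$pde[i])
    sol <- solve_steady_state(sc)
    k <- sc$kinetics
    hydrolysis <- k$kcat * sc$pde_tot * sc$l_star * sol$b / (k$km + sol$b)
    expect_equal(hydrolysis, sc$j_b, tolerance = 1e-10)
    expect_equal(sol$a, sc$j_b * sc$l_star / sc$d)
  }
})

test_that("no bounded steady state when catalytic capacity cannot absorb the influx", {
  sc <- barrier_scenario(d = 300, pde_tot = 1)  # Vmax ~ 1.47 < j_b ~ 4.98
  expect_error(solve_steady_state(sc), "no bounded steady state")
  # zero influx has the trivial steady state
  sc0 <- barrier_scenario(d = 300, j_b = 0, pde_tot = 1)
  expect_identical(solve_steady_state(sc0)$r, 0)
})

test_that("profile is piecewise linear with the boundary values of the solution", {
  sol <- solve_steady_state(barrier_scenario(d = 60))
  sc <- sol$scenario
  expect_equal(profile_at(sol, 0), sol$a + sol$b)
  expect_equal(profile_at(sol, sc$l_star), sol$b)
  expect_equal(profile_at(sol, sc$l_total), sol$b)
  expect_equal(profile_at(sol, sc$l_star / 2), sol$a / 2 + sol$b)
  # continuous and non-increasing
  z <- seq(0, sc$l_total, length.out = 200)
  p <- profile_at(sol, z)
  expect_true(all(diff(p) <= 1e-12))
  expect_error(profile_at(sol, -0.01), "within")
  expect_error(profile_at(sol, sc$l_total + 0.01), "within")
})

test_that("R saturates in the limits of strong barrier and fast diffusion", {
  r_huge_pde <- solve_steady_state(barrier_scenario(d = 300, pde_tot = 1e12))$r
  expect_gt(r_huge_pde, 0.999999)
  r_fast_d <- solve_steady_state(barrier_scenario(d = 1e9))$r
  expect_lt(r_fast_d, 1e-9)
})

test_that("R is monotone in PDE concentration and diffusion coefficient", {
  pde_grid <- 10^seq(0.8, 4.6, length.out = 40)  # all above solvability
  for (d in c(300, 10)) {
    r <- vapply(pde_grid, function(p)
      solve_steady_state(barrier_scenario(d = d, pde_tot = p))$r, numeric(1))
    expect_true(all(diff(r) > 0))
  }
  d_grid <- c(1, 3, 10, 30, 100, 300, 1000)
  r_d <- vapply(d_grid, function(d)
    solve_steady_state(barrier_scenario(d = d))$r, numeric(1))
  expect_true(all(diff(r_d) < 0))
})

test_that("sensitivity sweep: zero perturbation is the identity, j_b is inert", {
  base <- barrier_scenario(d = 300)
  grid <- pde_count_to_concentration(c(100, 1000))
  sw0 <- sensitivity_sweep(base, grid, perturbation = 0)
  expect_true(all(sw0$delta == 0))
  # in the Vmax >> j_b regime the production rate barely moves R
  sw <- sensitivity_sweep(base, pde_count_to_concentration(10^(2:5)),
                          perturbation = 0.2)
  jb_rows <- sw[sw$parameter == "j_b", ]
  expect_lt(max(abs(jb_rows$delta)), 1e-3)
})

test_that("perturbed scenarios that lose solvability are reported, not fatal", {
  base <- barrier_scenario(d = 300)
  # Vmax/j_b ~ 1.23 at this concentration: the -20% kcat arm loses solvability
  sw <- sensitivity_sweep(base, pde_grid = 4.1514, perturbation = 0.2)
  kcat_minus <- sw[sw$parameter == "kcat" & sw$sign == -1, ]
  expect_true(is.na(kcat_minus$r_perturbed))
  expect_true(all(is.finite(sw$r_default)))
})

test_that("R stays insensitive over the physiological PDE range", {
  # across 1..100 uM PDE every +-20% parameter change moves R by < 0.06
  grid <- 10^seq(log10(4.2), 2, length.out = 15)
  for (d in c(300, 60, 10)) {
    sw <- sensitivity_sweep(barrier_scenario(d = d), grid)
    expect_lt(max(abs(sw$delta), na.rm = TRUE), 0.06)
  }
})
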