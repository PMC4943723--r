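test_that("geometry voxelises the cleft, shell and source consistently", {
  g <- small_dyad_geometry()
  # cleft interior is cytosol with the expected voxelised volume
  cleft_vox <- prod(lengths(g$cleft_index))
  expect_equal(cleft_vox * g$spacing^3,
               prod(round(c(1.04, 0.765, 0.415) / g$spacing)) * g$spacing^3)
  expect_true(all(g$mask[g$cleft_index$x, g$cleft_index$y, g$cleft_index$z] == 0L))
  # shell is a hollow sphere of cytosol voxels enclosing the source
  expect_true(all(g$mask[g$shell] == 0L))
  expect_true(all(g$mask[g$source] == 0L))
  expect_gt(sum(g$shell), 0)
  expect_equal(sum(g$source), 2L)  # 50 x 25 x 25 nm box at 25 nm spacing
  # shell volume to concentration composes with the unit module
  expect_equal(molecules_to_concentration(100, g$shell_volume),
               100 / (602.214076 * g$shell_volume), tolerance = 1e-12)
  # no obstacles requested: an all-cytosol box
  g0 <- small_dyad_geometry(with_obstacles = FALSE)
  expect_identical(sum(g0$mask), 0L)
  expect_error(dyad_geometry(spacing = 0.05), "25 nm|spacing")
})

test_that("obstacles do not disconnect the cytosol", {
  g <- small_dyad_geometry()
  # flood fill from a source voxel must reach the far cytosol
  dims <- g$dims
  open <- g$mask == 0L
  visited <- array(FALSE, dims)
  start <- which(g$source)[1]
  queue <- start
  visited[start] <- TRUE
  nxy <- dims[1] * dims[2]
  offsets <- c(-1, 1, -dims[1], dims[1], -nxy, nxy)
  n <- prod(dims)
  while (length(queue)) {
    cur <- queue
    queue <- integer(0)
    for (off in offsets) {
      nb <- cur + off
      ok <- nb >= 1 & nb <= n
      # forbid x/y wrap-around
      if (off == -1) ok <- ok & (cur - 1) %% dims[1] != 0
      if (off == 1) ok <- ok & cur %% dims[1] != 0
      if (off == -dims[1]) ok <- ok & ((cur - 1) %/% dims[1]) %% dims[2] != 0
      if (off == dims[1]) ok <- ok & ((cur - 1) %/% dims[1]) %% dims[2] != dims[2] - 1
      nb <- nb[ok]
      nb <- nb[open[nb] & !visited[nb]]
      visited[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  expect_true(all(visited[g$far]))
})

test_that("degenerate scenarios are flagged", {
  g <- small_dyad_geometry()
  expect_error(run_dyad(dyad_scenario(d = 10, n_pde = 0, geometry = g)),
               "no bounded steady state")
  # zero source has the trivial zero steady state
  r0 <- run_dyad(dyad_scenario(d = 10, n_pde = 100, geometry = g,
                               source_rate = 0))
  expect_true(all(r0$field == 0))
})

test_that("steady state balances source and shell degradation, deterministically", {
  g <- small_dyad_geometry()
  r1 <- run_dyad(dyad_scenario(d = 60, n_pde = 1000, geometry = g))
  expect_equal(r1$balance, 1, tolerance = 1e-3)  # 0.1%
  expect_true(all(r1$field >= 0))
  # obstacle voxels carry no concentration: no leakage through their faces
  expect_true(all(r1$field[g$mask == 1L] == 0))
  r2 <- run_dyad(dyad_scenario(d = 60, n_pde = 1000, geometry = g))
  expect_identical(r1$field, r2$field)
})

test_that("gradient drop is monotone non-increasing in the diffusion coefficient", {
  g <- small_dyad_geometry()
  drops <- vapply(c(10, 60, 200), function(d)
    run_dyad(dyad_scenario(d = d, n_pde = 1000, geometry = g))$drop,
    numeric(1))
  expect_true(all(diff(drops) < 0))
})

test_that("anatomical obstacles never weaken the steady-state gradient", {
  # in a closed domain the far-cytosol level is pinned by the shell
  # absorption balance, so at steady state the obstacle effect on the
  # relative drop is non-negative but close to zero (see methods vignette)
  sc <- dyad_scenario(d = 10, n_pde = 100, geometry = small_dyad_geometry())
  eff <- obstacle_effect(sc)
  expect_gte(eff$drop_difference, -1e-3)
  expect_true(eff$with_obstacles$significant)
  expect_identical(sum(eff$without_obstacles$scenario$geometry$mask), 0L)
})

test_that("halving the voxel size moves the inside/outside ratio by < 5%", {
  sc1 <- dyad_scenario(d = 10, n_pde = 1000,
                       geometry = small_dyad_geometry(spacing = 0.025))
  sc2 <- dyad_scenario(d = 10, n_pde = 1000,
                       geometry = small_dyad_geometry(spacing = 0.0125))
  r1 <- run_dyad(sc1); r2 <- run_dyad(sc2)
  expect_equal(r1$ratio_interior, r2$ratio_interior, tolerance = 0.05)
})
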