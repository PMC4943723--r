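# Shared fixtures for the test suite.

# Published compartmentation ratios of the 1D barrier model, one per
# (diffusion coefficient, PDE molecule count) cell of the stochastic-model
# figure grid.
published_r_table <- function() {
  data.frame(
    d = rep(c(300, 60, 10), times = 5),
    n_pde = rep(10^(1:5), each = 3),
    r = c(6.098e-5, 3.048e-4, 1.826e-3,
          3.040e-3, 1.502e-2, 8.381e-2,
          3.188e-2, 1.414e-1, 4.970e-1,
          2.491e-1, 6.239e-1, 9.087e-1,
          7.685e-1, 9.432e-1, 9.901e-1))
}

# A small washout-free sarcomere geometry for fast solver tests.
small_geometry <- function() {
  sarcomere_geometry(width = 2, length = 10)
}

# Compact dyad geometry (reduced cytosol padding) for module-level tests;
# the acceptance suite exercises the full-size default geometry.
small_dyad_geometry <- function(spacing = 0.025, with_obstacles = TRUE) {
  dyad_geometry(spacing = spacing, padding = 0.3,
                with_obstacles = with_obstacles)
}

# Synthetic frame-count container mimicking a z_profile, built from an exact
# concentration profile (identical frames), for fitter tests.
synthetic_profile <- function(conc, scenario, n_frames = 50) {
  nb <- scenario$nbins
  edges <- seq(0, scenario$box[3], length.out = nb + 1)
  binvol <- diff(edges) * scenario$box[1] * scenario$box[2]
  counts <- matrix(rep(concentration_to_molecules(conc, binvol),
                       each = n_frames), n_frames, nb)
  prof <- data.frame(z_lo = edges[-(nb + 1)], z_hi = edges[-1],
                     z_mid = (edges[-1] + edges[-(nb + 1)]) / 2,
                     mean_uM = conc)
  structure(prof, counts = counts, binvol = binvol, n_frames = n_frames,
            scenario = scenario, class = c("z_profile", "data.frame"))
}
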