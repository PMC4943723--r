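## Stochastic Brownian-particle model of the PDE functional barrier: a
## 0.2 x 0.2 x 1.0 um reflective box, a caveolar source patch on the z = 0
## face emitting 120 molecules/s, and PDE sites on the plane z = 0.1 um.
##
## The binding machinery is calibrated against the macroscopic association
## rate: the per-encounter binding probability is
##   p = kf * sigma * sqrt(pi * dt / D) / (2 * Nc),
## where sigma is the surface site density and Nc converts uM um^3 to
## molecules.  A particle whose step straddles the plane is tested against
## the site occupying the lattice cell beneath the crossing point, within a
## capture radius r_c = (pi * sigma)^(-1/2) (each capture disc has area
## 1/sigma, so a fully occupied lattice tiles the plane).  Because the disc
## does not cover its rectangular lattice cell exactly, the run divides p by
## the disc-in-cell coverage fraction, which keeps the well-mixed association
## rate exactly on the macroscopic target.

#' Surface site density for a given PDE count
#'
#' The published density table for the barrier plane (positions/um^2):
#' 10 -> 1,500; 100 -> 2,500; 1,000 -> 25,000; 10,000 -> 250,000;
#' 100,000 -> 2,500,000.  For other counts the density packs the sites at
#' one per (area/n), so that the plane is exactly tiled.
#'
#' @param n_pde number of PDE sites.
#' @param plane_area area of the barrier plane, um^2.
#' @return Site density, positions/um^2.
#' @export
surface_grid_density <- function(n_pde, plane_area = 0.04) {
  table3 <- c(`10` = 1500, `100` = 2500, `1000` = 25000,
              `10000` = 250000, `1e+05` = 2500000)
  key <- as.character(n_pde)
  if (key %in% names(table3)) unname(table3[key]) else n_pde / plane_area
}

#' Per-encounter binding probability of the barrier machinery
#'
#' The probability with which a plane-crossing particle landing on a free PDE
#' site's capture disc binds, chosen so that in a well-mixed box the
#' simulated association rate recovers the macroscopic `kf [cAMP][PDE_free]`.
#' Scales as `sqrt(dt)` (diffusive encounter frequency scales as
#' `1/sqrt(dt)`).
#'
#' @param kinetics a [kinetic_constants()].
#' @param sigma surface site density, positions/um^2.
#' @param dt time step, s.
#' @param d diffusion coefficient, um^2/s.
#' @return The per-encounter probability (may exceed 1 for inadmissible dt).
#' @export
calibrate_binding <- function(kinetics, sigma, dt, d) {
  stopifnot(inherits(kinetics, "kinetic_constants"),
            sigma > 0, dt > 0, d > 0)
  kinetics$kf * sigma * sqrt(pi * dt / d) / (2 * MOLECULES_PER_UM_UM3)
}

#' Largest admissible time step for the barrier machinery
#'
#' The largest `dt` for which the calibrated per-encounter binding
#' probability stays at or below `cap`.  Larger site densities require
#' smaller steps; faster diffusion admits larger ones.
#'
#' @inheritParams calibrate_binding
#' @param cap probability cap (default 0.5).
#' @return Maximum admissible `dt`, s.
#' @export
admissible_dt <- function(kinetics, sigma, d, cap = 0.5) {
  stopifnot(cap > 0)
  (2 * cap * MOLECULES_PER_UM_UM3 / (kinetics$kf * sigma))^2 * d / pi
}

## fraction of a centred rectangle (ax x ay) covered by a disc of radius r_c,
## by deterministic midpoint quadrature
capture_coverage <- function(r_c, ax, ay, n = 400L) {
  xs <- (seq_len(n) - 0.5) / n * ax - ax / 2
  ys <- (seq_len(n) - 0.5) / n * ay - ay / 2
  mean(outer(xs^2, ys^2, `+`) <= r_c^2)
}

## near-square factorisation nx * ny = ncell with nx/ny ~ lx/ly
lattice_dims <- function(ncell, lx, ly) {
  target <- sqrt(ncell * lx / ly)
  divs <- which(ncell %% seq_len(ncell) == 0)
  nx <- divs[which.min(abs(divs - target))]
  c(nx = nx, ny = ncell %/% nx)
}

#' Scenario for the 3D stochastic barrier simulation
#'
#' @param d cAMP diffusion coefficient, um^2/s.
#' @param n_pde number of PDE sites on the barrier plane.
#' @param dt time step, s.  The default 1e-6 s relies on the calibrated
#'   binding probability; admissibility is checked against `p_cap`.
#' @param duration simulated time, s.
#' @param frame_interval interval between recorded frames, s.
#' @param sigma surface site density (default from
#'   [surface_grid_density()]).
#' @param source_rate emission rate of the caveolar patch, molecules/s.
#' @param box box dimensions `c(lx, ly, lz)`, um.
#' @param l_star barrier plane position, um.
#' @param patch caveolar patch side length (centred on the z = 0 face), um.
#' @param kinetics a [kinetic_constants()].
#' @param nbins number of z bins for recorded profiles.
#' @param p_cap admissibility cap on the per-encounter probability.
#' @param init_n initial number of uniformly placed particles.
#' @return Object of class `particle_scenario`.
#' @export
particle_scenario <- function(d, n_pde, dt = 1e-6, duration = 3,
                              frame_interval = 5e-3,
                              sigma = surface_grid_density(n_pde),
                              source_rate = 120,
                              box = c(0.2, 0.2, 1.0), l_star = 0.1,
                              patch = 0.1,
                              kinetics = kinetic_constants(),
                              nbins = 100L, p_cap = 1, init_n = 0L) {
  stopifnot(d > 0, n_pde >= 0, dt > 0, duration > 0, all(box > 0),
            l_star > 0, l_star < box[3])
  if (n_pde == 0) sigma <- max(sigma, 1 / (box[1] * box[2]))
  p <- calibrate_binding(kinetics, sigma, dt, d)
  if (n_pde > 0 && p > p_cap)
    stop(sprintf(paste0("dt = %g s is inadmissible: per-encounter binding ",
                        "probability %.3g exceeds the cap %.3g; use dt <= %g"),
                 dt, p, p_cap, admissible_dt(kinetics, sigma, d, p_cap)))
  structure(list(d = d, n_pde = as.integer(n_pde), dt = dt,
                 duration = duration, frame_interval = frame_interval,
                 sigma = sigma, source_rate = source_rate, box = box,
                 l_star = l_star, patch = patch, kinetics = kinetics,
                 nbins = as.integer(nbins), p_bind = p,
                 init_n = as.integer(init_n)),
            class = "particle_scenario")
}

#' @export
print.particle_scenario <- function(x, ...) {
  cat(sprintf(paste0("particle scenario: D = %g um^2/s, %d PDE sites ",
                     "(sigma = %g /um^2), dt = %g s, %g s, p_bind = %.3g\n"),
              x$d, x$n_pde, x$sigma, x$dt, x$duration, x$p_bind))
  invisible(x)
}

## build the site lattice: indicator of occupied cells + geometry
build_site_lattice <- function(scenario) {
  lx <- scenario$box[1]; ly <- scenario$box[2]
  ncell <- max(1L, round(scenario$sigma * lx * ly))
  dims <- lattice_dims(ncell, lx, ly)
  occupied <- integer(ncell)
  if (scenario$n_pde >= ncell) {
    occupied[] <- 1L
    if (scenario$n_pde > ncell)
      warning("more PDE sites than lattice cells; using one per cell")
  } else if (scenario$n_pde > 0) {
    occupied[sample.int(ncell, scenario$n_pde)] <- 1L
  }
  r_c <- 1 / sqrt(pi * scenario$sigma)
  ax <- lx / dims["nx"]; ay <- ly / dims["ny"]
  list(nxs = unname(dims["nx"]), nys = unname(dims["ny"]),
       occupied = occupied, r_c = r_c,
       coverage = capture_coverage(r_c, ax, ay))
}

#' Run the stochastic barrier simulation
#'
#' Seed the R RNG (`set.seed`) before calling for reproducible runs; results
#' are bit-identical for a given seed and scenario.
#'
#' @param scenario a [particle_scenario()].
#' @return Object of class `particle_run`: frame-by-frame z-histogram counts,
#'   frame times, particle-count time course, exact bookkeeping counters
#'   (`produced`, `degraded`, `free_count`, `bound_count`), and the scenario.
#' @export
run_particle <- function(scenario) {
  stopifnot(inherits(scenario, "particle_scenario"))
  lat <- build_site_lattice(scenario)
  p_eff <- scenario$p_bind / lat$coverage
  if (scenario$n_pde > 0 && p_eff > 1)
    stop("coverage-corrected binding probability exceeds 1; reduce dt")
  half <- scenario$patch / 2
  cx <- scenario$box[1] / 2; cy <- scenario$box[2] / 2
  out <- .particle_run_cpp(
    scenario$box[1], scenario$box[2], scenario$box[3], scenario$l_star,
    scenario$d, scenario$dt, scenario$duration, scenario$frame_interval,
    scenario$source_rate, cx - half, cx + half, cy - half, cy + half,
    lat$nxs, lat$nys, lat$occupied, lat$r_c, p_eff,
    scenario$kinetics$kb, scenario$kinetics$kcat,
    scenario$init_n, scenario$nbins, FALSE)
  out$scenario <- scenario
  out$bin_edges <- seq(0, scenario$box[3], length.out = scenario$nbins + 1)
  class(out) <- "particle_run"
  out
}

#' @export
print.particle_run <- function(x, ...) {
  cat(sprintf(paste0("particle run: produced %g, degraded %g, free %g, ",
                     "bound %g (%d frames)\n"),
              x$produced, x$degraded, x$free_count, x$bound_count,
              length(x$frame_time)))
  invisible(x)
}

#' Time course of the spatially averaged concentration
#'
#' @param run a `particle_run`.
#' @return Data frame with `time` (s) and `mean_uM`.
#' @export
particle_time_course <- function(run) {
  v <- prod(run$scenario$box)
  data.frame(time = run$frame_time,
             mean_uM = molecules_to_concentration(run$frame_count, v))
}

#' Frame-averaged concentration profile along z
#'
#' Averages the recorded z-histograms over all frames in `window` (the
#' steady-state window) and converts counts to concentrations.
#'
#' @param run a `particle_run`.
#' @param window two times (s); frames with `window[1] <= t <= window[2]`
#'   enter the average.
#' @return Object of class `z_profile`: data frame columns `z_lo`, `z_hi`,
#'   `z_mid`, `mean_uM`, with the per-frame count matrix and frame count as
#'   attributes.
#' @export
z_profile <- function(run, window = c(1, Inf)) {
  sel <- run$frame_time >= window[1] & run$frame_time <= window[2]
  if (!any(sel)) stop("no frames in the requested window")
  counts <- run$frames[sel, , drop = FALSE]
  edges <- run$bin_edges
  binvol <- diff(edges) * run$scenario$box[1] * run$scenario$box[2]
  prof <- data.frame(z_lo = edges[-length(edges)], z_hi = edges[-1],
                     z_mid = (edges[-1] + edges[-length(edges)]) / 2,
                     mean_uM = molecules_to_concentration(
                       colMeans(counts), binvol))
  structure(prof, counts = counts, binvol = binvol,
            n_frames = sum(sel), scenario = run$scenario,
            class = c("z_profile", "data.frame"))
}

## least-squares fit of the piecewise barrier profile to binned means:
## c(z) = b + a * max(1 - z/l_star, 0)
fit_barrier_profile <- function(z_mid, conc, l_star) {
  u <- pmax(1 - z_mid / l_star, 0)
  fit <- stats::lm.fit(cbind(intercept = 1, u = u), conc)
  b <- fit$coefficients[["intercept"]]
  a <- fit$coefficients[["u"]]
  list(a = a, b = b, r = a / (a + b))
}

#' Estimate the compartmentation ratio from a stochastic profile
#'
#' Fits the piecewise steady-state shape (linear from `a+b` at z = 0 down to
#' `b` at the barrier, constant beyond) to the frame-averaged profile and
#' returns the ratio `a/(a+b)` with a bootstrap-over-frames standard error.
#'
#' @param profile a [z_profile()].
#' @param n_boot bootstrap resamples of frames (default 200).
#' @return List with `r`, `se`, `a`, `b`, `n_frames`, and `flagged` (TRUE
#'   when the fitted plateau is non-positive, a degenerate fit).
#' @export
estimate_r <- function(profile, n_boot = 200L) {
  stopifnot(inherits(profile, "z_profile"))
  sc <- attr(profile, "scenario")
  counts <- attr(profile, "counts")
  binvol <- attr(profile, "binvol")
  l_star <- sc$l_star
  if (!any(profile$z_mid < l_star) || !any(profile$z_mid > l_star))
    stop("profile needs bins on both sides of the barrier plane")
  fit <- fit_barrier_profile(profile$z_mid, profile$mean_uM, l_star)
  nf <- nrow(counts)
  boot <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(nf, nf, replace = TRUE)
    conc <- molecules_to_concentration(colMeans(counts[idx, , drop = FALSE]),
                                       binvol)
    fit_barrier_profile(profile$z_mid, conc, l_star)$r
  }, numeric(1))
  list(r = fit$r, se = stats::sd(boot), a = fit$a, b = fit$b,
       n_frames = nf, flagged = !is.finite(fit$r) || fit$b <= 0)
}

#' Well-mixed validation of the binding calibration
#'
#' Fills the box with a uniform population, disables the source and the
#' binding consequences (sites never occupy, particles never disappear), and
#' counts accepted binding encounters.  The measured association rate should
#' recover `kf [cAMP] [PDE]` — the macroscopic-rate contract of the
#' calibrated machinery.
#'
#' @param scenario a [particle_scenario()]; its source is ignored.
#' @param n_particles size of the uniform test population.
#' @param duration counting window, s.
#' @return List with `measured_kf`, `target_kf`, `ratio`, `events`, and the
#'   expected event count.
#' @export
validate_binding_rate <- function(scenario, n_particles = 2000L,
                                  duration = 0.05) {
  stopifnot(inherits(scenario, "particle_scenario"), scenario$n_pde > 0)
  lat <- build_site_lattice(scenario)
  p_eff <- scenario$p_bind / lat$coverage
  half <- scenario$patch / 2
  cx <- scenario$box[1] / 2; cy <- scenario$box[2] / 2
  out <- .particle_run_cpp(
    scenario$box[1], scenario$box[2], scenario$box[3], scenario$l_star,
    scenario$d, scenario$dt, duration, duration,
    0, cx - half, cx + half, cy - half, cy + half,
    lat$nxs, lat$nys, lat$occupied, lat$r_c, p_eff,
    scenario$kinetics$kb, scenario$kinetics$kcat,
    n_particles, scenario$nbins, TRUE)
  v <- prod(scenario$box)
  camp <- molecules_to_concentration(n_particles, v)
  ## events/s = kf [cAMP] * n_sites / 1 (per-site formulation):
  ## kf [cAMP][PDE] V Nc = kf [cAMP] n_sites
  expected <- scenario$kinetics$kf * camp * scenario$n_pde * duration
  measured_kf <- scenario$kinetics$kf * out$bind_events / expected
  list(measured_kf = measured_kf, target_kf = scenario$kinetics$kf,
       ratio = out$bind_events / expected, events = out$bind_events,
       expected_events = expected)
}
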