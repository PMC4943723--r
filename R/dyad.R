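## Idealized 3D continuum model of a cardiac dyadic cleft.  The cleft
## (~1040 x 765 x 415 nm) is framed by impermeable anatomical obstacles —
## a t-tubule slab below, a junctional-SR slab above, and two mitochondrion
## blocks flanking it — and opens into surrounding cytosol along the
## remaining faces.  An adenylyl-cyclase cluster (15 AC molecules, 120
## molecules/s total) sits at the cleft centre, surrounded by a hollow
## sphere of PDEs (outer diameter 200 nm, 25 nm thick).  The steady state of
## diffusion + Michaelis-Menten degradation is solved on a voxel grid by the
## compiled conjugate-gradient solver.

#' Synthetic voxel geometry of the dyadic cleft
#'
#' A deterministic, parametric stand-in for segmented electron-tomography
#' anatomy: every structure is an axis-aligned block or a voxelised sphere.
#' Dimensions are snapped to whole voxels; the defaults reproduce the target
#' cleft dimensions to within half a voxel.
#'
#' @param spacing voxel edge length, um (<= 0.025).
#' @param cleft cleft dimensions `c(x, y, z)`, um.
#' @param padding cytosol padding beyond the obstacle frame on every axis,
#'   um.
#' @param obstacle_thickness thickness of the t-tubule/SR/mitochondrion
#'   blocks, um.
#' @param shell_outer_radius outer radius of the hollow PDE sphere, um
#'   (0.1 = 200 nm diameter; set 0.025 for the compact-sphere variant).
#' @param shell_thickness shell thickness, um.
#' @param source_box dimensions of the box-shaped AC source region at the
#'   cleft centre, um (a fixed physical region, snapped to multiples of its
#'   own dimensions so that refined grids reproduce it exactly).
#' @param with_obstacles logical; `FALSE` yields an all-cytosol box of the
#'   same dimensions (for paired obstacle-effect runs).
#' @return Object of class `dyad_geometry`: the obstacle `mask` (0 cytosol,
#'   1 obstacle, array nx x ny x nz), logical arrays `shell` and `source`,
#'   voxel `spacing`, `shell_volume`, `source_volume`, cytosol volume, and
#'   the index sets used for reporting (`far` = cytosol outside the
#'   obstacle-frame bounding box).
#' @export
dyad_geometry <- function(spacing = 0.025,
                          cleft = c(1.040, 0.765, 0.415),
                          padding = 1.0,
                          obstacle_thickness = 0.1,
                          shell_outer_radius = 0.1,
                          shell_thickness = 0.025,
                          source_box = c(0.05, 0.025, 0.025),
                          with_obstacles = TRUE) {
  args <- list(spacing = spacing, cleft = cleft, padding = padding,
               obstacle_thickness = obstacle_thickness,
               shell_outer_radius = shell_outer_radius,
               shell_thickness = shell_thickness, source_box = source_box)
  if (spacing > 0.025 + 1e-12)
    stop("spacing must be <= 0.025 um to resolve the 25 nm PDE shell")
  if (shell_thickness < spacing - 1e-12)
    stop("spacing too coarse to form the PDE shell")
  h <- spacing
  nvc <- pmax(1L, round(cleft / h))          # cleft voxels per axis
  npad <- round(padding / h)
  nob <- round(obstacle_thickness / h)
  nx <- nvc[1] + 2L * nob + 2L * npad
  ny <- nvc[2] + 2L * npad
  nz <- nvc[3] + 2L * nob + 2L * npad
  ## voxel centre coordinates
  xc <- (seq_len(nx) - 0.5) * h
  yc <- (seq_len(ny) - 0.5) * h
  zc <- (seq_len(nz) - 0.5) * h
  ## cleft interior index ranges
  ix <- (npad + nob + 1L):(npad + nob + nvc[1])
  iy <- (npad + 1L):(npad + nvc[2])
  iz <- (npad + nob + 1L):(npad + nob + nvc[3])
  mask <- array(0L, dim = c(nx, ny, nz))
  if (with_obstacles) {
    ## t-tubule below / junctional SR above the cleft (z), spanning the
    ## cleft footprint; mitochondria flanking in x, spanning cleft + slabs
    zlo <- (npad + 1L):(npad + nob)
    zhi <- (npad + nob + nvc[3] + 1L):(npad + 2L * nob + nvc[3])
    mask[ix, iy, zlo] <- 1L
    mask[ix, iy, zhi] <- 1L
    xlo <- (npad + 1L):(npad + nob)
    xhi <- (npad + nob + nvc[1] + 1L):(npad + 2L * nob + nvc[1])
    zfull <- (npad + 1L):(npad + 2L * nob + nvc[3])
    mask[xlo, iy, zfull] <- 1L
    mask[xhi, iy, zfull] <- 1L
  }
  centre <- c(mean(range(xc[ix])), mean(range(yc[iy])), mean(range(zc[iz])))
  dist2 <- outer(outer((xc - centre[1])^2, (yc - centre[2])^2, `+`),
                 (zc - centre[3])^2, `+`)
  r_in <- shell_outer_radius - shell_thickness
  shell <- dist2 > r_in^2 & dist2 <= shell_outer_radius^2
  ## AC source: a box snapped per axis to multiples of its own dimensions,
  ## so that refined voxel grids (h dividing the box sides) reproduce
  ## exactly the same physical source region
  source <- array(FALSE, dim = c(nx, ny, nz))
  lo <- floor(centre / source_box) * source_box
  source[xc > lo[1] & xc < lo[1] + source_box[1],
         yc > lo[2] & yc < lo[2] + source_box[2],
         zc > lo[3] & zc < lo[3] + source_box[3]] <- TRUE
  if (!any(source)) stop("empty source region; check spacing")
  if (any(mask[shell] != 0L)) stop("PDE shell intersects an obstacle")
  if (any(mask[source] != 0L)) stop("source region intersects an obstacle")
  if (!all(dist2[source] <= r_in^2))
    stop("PDE shell does not enclose the source region")
  ## far cytosol: outside the obstacle-frame bounding box
  frame_x <- range(c(ix, if (with_obstacles) c(npad + 1L, npad + 2L * nob + nvc[1])))
  frame_z <- range(c(iz, if (with_obstacles) c(npad + 1L, npad + 2L * nob + nvc[3])))
  in_frame <- array(FALSE, dim = c(nx, ny, nz))
  in_frame[frame_x[1]:frame_x[2], iy, frame_z[1]:frame_z[2]] <- TRUE
  far <- !in_frame & mask == 0L
  interior <- dist2 <= r_in^2 & !shell & mask == 0L
  vox <- h^3
  structure(list(spacing = h, dims = c(nx, ny, nz), mask = mask,
                 shell = shell, source = source, far = far,
                 interior = interior, args = args,
                 centre = centre, cleft_index = list(x = ix, y = iy, z = iz),
                 shell_volume = sum(shell) * vox,
                 source_volume = sum(source) * vox,
                 cytosol_volume = sum(mask == 0L) * vox,
                 obstacle_volume = sum(mask == 1L) * vox,
                 with_obstacles = with_obstacles),
            class = "dyad_geometry")
}

#' @export
print.dyad_geometry <- function(x, ...) {
  cat(sprintf(paste0("dyad geometry: %d x %d x %d voxels at %g nm ",
                     "(cytosol %.3g um^3, obstacles %.3g um^3, shell %d ",
                     "voxels, source %d voxels)\n"),
              x$dims[1], x$dims[2], x$dims[3], x$spacing * 1e3,
              x$cytosol_volume, x$obstacle_volume, sum(x$shell),
              sum(x$source)))
  invisible(x)
}

#' Scenario for the dyadic-cleft continuum model
#'
#' @param d cAMP diffusion coefficient, um^2/s.
#' @param n_pde number of PDE molecules in the shell; the shell concentration
#'   is derived from the count and the voxelised shell volume.
#' @param geometry a [dyad_geometry()].
#' @param source_rate total AC emission, molecules/s.
#' @param kinetics a [kinetic_constants()] (single-species PDE kinetics).
#' @return Object of class `dyad_scenario`.
#' @export
dyad_scenario <- function(d, n_pde, geometry = dyad_geometry(),
                          source_rate = 120,
                          kinetics = kinetic_constants()) {
  stopifnot(inherits(geometry, "dyad_geometry"), d > 0, n_pde >= 0,
            source_rate >= 0)
  structure(list(d = d, n_pde = n_pde, geometry = geometry,
                 source_rate = source_rate, kinetics = kinetics),
            class = "dyad_scenario")
}

#' Solve the dyadic-cleft model to steady state
#'
#' Finite-volume diffusion with no-flux conditions at obstacle faces and the
#' domain boundary, a constant source in the AC voxels, and a
#' Michaelis-Menten sink in the PDE shell voxels.  Reports the steady-state
#' field, the concentration at the production site, inside the shell, and in
#' the far cytosol, and the 15% gradient classification (significant when
#' the far-cytosol concentration falls more than 15% below the
#' production-site concentration).
#'
#' @param scenario a [dyad_scenario()].
#' @param cg_tol relative residual tolerance of the inner linear solver.
#' @param picard_tol relative-change tolerance of the Michaelis-Menten
#'   fixed-point iteration.
#' @param max_picard maximum Picard iterations.
#' @return Object of class `dyad_result` with the field (3D array, uM), the
#'   summary metrics, and solver diagnostics.
#' @export
run_dyad <- function(scenario, cg_tol = 1e-9, picard_tol = 1e-7,
                     max_picard = 25L) {
  stopifnot(inherits(scenario, "dyad_scenario"))
  g <- scenario$geometry
  if (scenario$n_pde == 0 && scenario$source_rate > 0)
    stop(paste("no bounded steady state: constant source with no PDE sink;",
               "concentration grows without bound"))
  vox <- g$spacing^3
  shell_conc <- if (scenario$n_pde > 0)
    molecules_to_concentration(scenario$n_pde, g$shell_volume) else 0
  vmax <- array(0, dim = g$dims)
  vmax[g$shell] <- scenario$kinetics$kcat * shell_conc
  src <- array(0, dim = g$dims)
  src[g$source] <- molecules_to_concentration(
    scenario$source_rate / sum(g$source), vox)  # uM/s per source voxel
  sol <- .dyad_solve_cpp(as.integer(g$mask), g$dims[1], g$dims[2], g$dims[3],
                         g$spacing, scenario$d, as.numeric(src),
                         as.numeric(vmax), scenario$kinetics$km,
                         cg_tol, 20000L, picard_tol, max_picard)
  if (!sol$converged)
    stop("steady-state solve did not converge; Picard relative change = ",
         sol$rel_change)
  field <- array(sol$c, dim = g$dims)
  conc_source <- mean(field[g$source])
  conc_shell_interior <- mean(field[g$interior])
  conc_shell <- mean(field[g$shell])
  conc_far <- mean(field[g$far])
  drop <- if (conc_source > 0) (conc_source - conc_far) / conc_source else 0
  degr_total <- sum(vmax * field / (scenario$kinetics$km + field)) * vox
  src_total <- sum(src) * vox
  structure(list(field = field, scenario = scenario,
                 conc_source = conc_source,
                 conc_shell_interior = conc_shell_interior,
                 conc_shell = conc_shell, conc_far = conc_far,
                 drop = drop, ratio = conc_far / conc_source,
                 ratio_interior = conc_far / conc_shell_interior,
                 significant = drop > 0.15,
                 source_total = src_total, degradation_total = degr_total,
                 balance = degr_total / src_total,
                 shell_conc = shell_conc,
                 diagnostics = sol[c("picard_iters", "cg_iters",
                                     "rel_change", "converged")]),
            class = "dyad_result")
}

#' @export
print.dyad_result <- function(x, ...) {
  cat(sprintf(paste0("dyad steady state: D = %g um^2/s, %g PDEs ",
                     "(%.4g uM in shell); source %.4g uM, far %.4g uM, ",
                     "drop %.1f%% -> %s\n"),
              x$scenario$d, x$scenario$n_pde, x$shell_conc, x$conc_source,
              x$conc_far, 100 * x$drop,
              if (x$significant) "significant gradient" else "no significant gradient"))
  invisible(x)
}

#' Paired gradient metrics with and without anatomical obstacles
#'
#' Runs the same scenario on the obstacle geometry and on an all-cytosol box
#' of identical dimensions, and returns both gradient metrics.  Restricted
#' anatomy can only hinder escape from the source, so the with-obstacle drop
#' is at least the without-obstacle drop.
#'
#' @param scenario a [dyad_scenario()] built on an obstacle geometry.
#' @param ... passed to [run_dyad()].
#' @return List with `with_obstacles`, `without_obstacles` (both
#'   `dyad_result`) and `drop_difference`.
#' @export
obstacle_effect <- function(scenario, ...) {
  stopifnot(inherits(scenario, "dyad_scenario"))
  g <- scenario$geometry
  g0 <- do.call(dyad_geometry, c(g$args, list(with_obstacles = FALSE)))
  sc0 <- dyad_scenario(d = scenario$d, n_pde = scenario$n_pde,
                       geometry = g0, source_rate = scenario$source_rate,
                       kinetics = scenario$kinetics)
  with_obs <- run_dyad(scenario, ...)
  without_obs <- run_dyad(sc0, ...)
  list(with_obstacles = with_obs, without_obstacles = without_obs,
       drop_difference = with_obs$drop - without_obs$drop)
}
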