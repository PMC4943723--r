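## One-dimensional steady-state functional-barrier model.
##
## A membrane at z = 0 injects cAMP at areal flux J_B into a column of length
## l_total; all PDE sits in a thin layer ("barrier plane") at z = l_star.
## At steady state the barrier must hydrolyse exactly what the membrane
## injects, which fixes the plateau concentration B behind the barrier via
## Michaelis-Menten flux balance
##
##   J_B = kcat * (PDE_tot * l_star) * B / (Km + B),
##
## i.e. B = Km * J_B / (kcat * PDE_tot * l_star - J_B), while the diffusive
## gradient that carries the flux to the barrier sets the linear drop
## A = J_B * l_star / D.  The profile is linear from A + B at z = 0 down to B
## at z = l_star and flat beyond.  The compartmentation ratio R = A/(A+B)
## measures how much of the cAMP is held in front of the barrier: R = 0 means
## a uniform column, R = 1 means complete trapping.

#' Default cAMP influx of the barrier models (uM um / s)
#'
#' 120 molecules/s emitted over the 0.2 x 0.2 um cross-section, converted
#' exactly (~4.982 uM um/s).
#' @export
default_jb <- function() source_rate_to_flux(120, 0.2 * 0.2)

#' PDE barrier concentration corresponding to a molecule count
#'
#' Concentration averaged over the pre-barrier region (cross-section
#' 0.2 x 0.2 um, depth l_star), the convention used for all barrier scenarios:
#' 10 molecules correspond to ~4.1514 uM at the default l_star = 0.1 um.
#'
#' @param n number of PDE molecules on the barrier plane.
#' @param l_star barrier depth in um.
#' @param cross_section cross-sectional area in um^2.
#' @return Concentration in uM.
#' @export
pde_count_to_concentration <- function(n, l_star = 0.1,
                                       cross_section = 0.2 * 0.2) {
  molecules_to_concentration(n, cross_section * l_star)
}

#' One-dimensional functional-barrier scenario
#'
#' @param d cAMP diffusion coefficient, um^2/s.
#' @param l_star position of the PDE barrier plane, um.
#' @param l_total domain length, um.
#' @param j_b cAMP influx at z = 0, uM um/s.  The default is the exactly
#'   derived value for 120 molecules/s over 0.04 um^2.
#' @param pde_tot total PDE concentration averaged over `0 <= z <= l_star`, uM.
#' @param kinetics a [kinetic_constants()] object.
#' @return Object of class `barrier_scenario`.
#' @examples
#' sc <- barrier_scenario(d = 300, pde_tot = pde_count_to_concentration(100))
#' solve_steady_state(sc)$r
#' @export
barrier_scenario <- function(d, l_star = 0.1, l_total = 1.0,
                             j_b = default_jb(),
                             pde_tot = pde_count_to_concentration(100),
                             kinetics = kinetic_constants()) {
  stopifnot(inherits(kinetics, "kinetic_constants"))
  if (!(l_star > 0 && l_star < l_total)) stop("need 0 < l_star < l_total")
  if (d <= 0) stop("diffusion coefficient must be > 0")
  if (j_b < 0) stop("j_b must be >= 0")
  if (pde_tot < 0) stop("pde_tot must be >= 0")
  structure(list(d = d, l_star = l_star, l_total = l_total, j_b = j_b,
                 pde_tot = pde_tot, kinetics = kinetics),
            class = "barrier_scenario")
}

#' Solve the 1D functional-barrier model at steady state
#'
#' Returns the linear-drop amplitude `a`, the plateau `b`, the
#' compartmentation ratio (field `r`, equal to `a/(a+b)`), and the
#' piecewise-linear profile.
#' A bounded steady state requires the areal catalytic capacity
#' `kcat * pde_tot * l_star` to exceed the influx `j_b`; otherwise the barrier
#' cannot absorb what the membrane injects and no steady state exists.
#'
#' @param scenario a [barrier_scenario()].
#' @return Object of class `barrier_solution` with fields `a`, `b`, `r`,
#'   and the scenario.
#' @export
solve_steady_state <- function(scenario) {
  stopifnot(inherits(scenario, "barrier_scenario"))
  k <- scenario$kinetics
  vmax_areal <- k$kcat * scenario$pde_tot * scenario$l_star  # uM um / s
  if (scenario$j_b == 0) {
    a <- 0; b <- 0
    r <- 0
  } else {
    if (vmax_areal <= scenario$j_b)
      stop(sprintf(paste0("no bounded steady state: areal Vmax (%.4g uM um/s)",
                          " does not exceed influx j_b (%.4g uM um/s);",
                          " deficit %.4g"),
                   vmax_areal, scenario$j_b, scenario$j_b - vmax_areal))
    a <- scenario$j_b * scenario$l_star / scenario$d
    b <- k$km * scenario$j_b / (vmax_areal - scenario$j_b)
    r <- a / (a + b)
  }
  structure(list(a = a, b = b, r = r, scenario = scenario),
            class = "barrier_solution")
}

#' @export
print.barrier_solution <- function(x, ...) {
  cat(sprintf("1D barrier steady state: A = %.4g uM, B = %.4g uM, R = %.4g\n",
              x$a, x$b, x$r))
  invisible(x)
}

#' Evaluate the steady-state cAMP profile
#'
#' Piecewise-linear: `(a+b) - (j_b/d) z` for `0 <= z <= l_star`, constant `b`
#' beyond the barrier.
#'
#' @param solution a `barrier_solution` from [solve_steady_state()].
#' @param z position(s) in um, within `[0, l_total]`.
#' @return Concentration(s) in uM.
#' @export
profile_at <- function(solution, z) {
  stopifnot(inherits(solution, "barrier_solution"))
  sc <- solution$scenario
  if (any(z < 0 | z > sc$l_total))
    stop("z must lie within [0, l_total]")
  ifelse(z <= sc$l_star,
         (solution$a + solution$b) - (sc$j_b / sc$d) * z,
         solution$b)
}

## Perturb one parameter of a scenario by a signed fraction.  The composite
## parameter D/(kf l_star) is perturbed through D alone: scaling kf or l_star
## instead would also change Km and the areal Vmax, which are physically
## distinct knobs (see the methods vignette).
perturb_scenario <- function(base, parameter, factor) {
  k <- base$kinetics
  switch(parameter,
    composite = barrier_scenario(d = base$d * factor, l_star = base$l_star,
                                 l_total = base$l_total, j_b = base$j_b,
                                 pde_tot = base$pde_tot, kinetics = k),
    kb = barrier_scenario(d = base$d, l_star = base$l_star,
                          l_total = base$l_total, j_b = base$j_b,
                          pde_tot = base$pde_tot,
                          kinetics = kinetic_constants(k$kf, k$kb * factor,
                                                       k$kcat)),
    kcat = barrier_scenario(d = base$d, l_star = base$l_star,
                            l_total = base$l_total, j_b = base$j_b,
                            pde_tot = base$pde_tot,
                            kinetics = kinetic_constants(k$kf, k$kb,
                                                         k$kcat * factor)),
    j_b = barrier_scenario(d = base$d, l_star = base$l_star,
                           l_total = base$l_total, j_b = base$j_b * factor,
                           pde_tot = base$pde_tot, kinetics = k),
    stop("unknown parameter: ", parameter)
  )
}

#' Parameter-sensitivity sweep of the compartmentation ratio
#'
#' Perturbs each of the four parameters `D/(kf l_star)` (through D), `kb`,
#' `kcat` and `j_b` by `+/- perturbation`, recomputes R over a grid of PDE
#' concentrations, and reports every `R_perturbed - R_default`.  Grid points
#' where a perturbed scenario loses its bounded steady state (areal Vmax no
#' longer exceeds the influx) are reported as `NA` rather than failing the
#' sweep.
#'
#' @param base a [barrier_scenario()]; its `pde_tot` is ignored in favour of
#'   `pde_grid`.
#' @param pde_grid PDE concentrations (uM) at which to evaluate R.
#' @param perturbation fractional perturbation (default 0.20).
#' @return A data frame with columns `parameter`, `sign`, `pde_tot`, `d`,
#'   `r_default`, `r_perturbed`, `delta`; attribute `max_abs_delta` holds the
#'   per-parameter maxima.
#' @examples
#' sw <- sensitivity_sweep(barrier_scenario(d = 300),
#'                         pde_grid = pde_count_to_concentration(10^(1:3)))
#' attr(sw, "max_abs_delta")
#' @export
sensitivity_sweep <- function(base, pde_grid, perturbation = 0.20) {
  stopifnot(inherits(base, "barrier_scenario"), all(pde_grid > 0),
            perturbation >= 0)
  params <- c("composite", "kb", "kcat", "j_b")
  rows <- list()
  for (p in pde_grid) {
    sc0 <- barrier_scenario(d = base$d, l_star = base$l_star,
                            l_total = base$l_total, j_b = base$j_b,
                            pde_tot = p, kinetics = base$kinetics)
    r0 <- tryCatch(solve_steady_state(sc0)$r, error = function(e) NA_real_)
    for (par in params) {
      for (sgn in c(1, -1)) {
        scp <- perturb_scenario(sc0, par, 1 + sgn * perturbation)
        rp <- tryCatch(solve_steady_state(scp)$r, error = function(e) NA_real_)
        rows[[length(rows) + 1L]] <-
          data.frame(parameter = par, sign = sgn, pde_tot = p, d = base$d,
                     r_default = r0, r_perturbed = rp, delta = rp - r0)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "max_abs_delta") <-
    vapply(split(abs(out$delta), out$parameter),
           function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE),
           numeric(1))
  out
}

#' Log-spaced PDE concentration grid for sensitivity plots
#'
#' 50 points per decade from 1 to 1e5 uM, plus the five exactly derived
#' barrier-plane concentrations for 10^1..10^5 molecules.
#'
#' @return Sorted numeric vector of concentrations (uM).
#' @export
sensitivity_grid <- function() {
  g <- 10^seq(0, 5, by = 1 / 50)
  sort(unique(c(g, pde_count_to_concentration(10^(1:5)))))
}
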