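## Named scenario presets binding each figure-style experiment to a module
## and a parameter set, plus a light run-record mechanism so that outputs
## are traceable to a configuration and seed.  The R functions themselves
## are the entry points; `run_preset()` is a thin dispatcher over them.

preset_registry <- function() {
  particle_preset <- function(d, n_pde) {
    list(module = "particle_3d",
         config = list(d = d, n_pde = n_pde, dt = 1e-6, duration = 3,
                       window_start = 1, frame_interval = 5e-3),
         run = function(cfg) {
           sc <- particle_scenario(d = cfg$d, n_pde = cfg$n_pde, dt = cfg$dt,
                                   duration = cfg$duration,
                                   frame_interval = cfg$frame_interval)
           run <- run_particle(sc)
           prof <- z_profile(run, window = c(cfg$window_start, Inf))
           est <- estimate_r(prof)
           analytic <- solve_steady_state(barrier_scenario(
             d = cfg$d, pde_tot = pde_count_to_concentration(cfg$n_pde)))
           list(run = run, profile = prof, estimate = est,
                time_course = particle_time_course(run),
                analytic_r = analytic$r,
                z = if (est$se > 0) (est$r - analytic$r) / est$se else NA)
         })
  }
  stim_preset <- function(d, pde_scale) {
    list(module = "sarcomere_2d",
         config = list(d = d, pde_scale = pde_scale, duration = 2),
         run = function(cfg) run_scenario_stimulation(
           d = cfg$d, pde_scale = cfg$pde_scale, duration = cfg$duration))
  }
  washout_preset <- function(d) {
    list(module = "sarcomere_2d",
         config = list(d = d, pde_scale = 10),
         run = function(cfg) run_scenario_washout(d = cfg$d,
                                                  pde_scale = cfg$pde_scale))
  }
  p <- list(
    fig2_a = stim_preset(300, 0), fig2_b = stim_preset(300, 1),
    fig2_c = stim_preset(300, 10), fig2_d = stim_preset(60, 10),
    fig2_e = stim_preset(10, 10),
    s1_a = stim_preset(60, 1), s1_b = stim_preset(10, 1),
    s2_a = washout_preset(300), s2_b = washout_preset(60),
    s2_c = washout_preset(10),
    fig5 = list(module = "barrier_analytic",
                config = list(d = c(300, 60, 10), perturbation = 0.2),
                run = function(cfg) {
                  grids <- lapply(cfg$d, function(d)
                    sensitivity_sweep(barrier_scenario(d = d),
                                      pde_grid = sensitivity_grid(),
                                      perturbation = cfg$perturbation))
                  names(grids) <- paste0("d", cfg$d)
                  grids
                }),
    fig7_grid = list(module = "dyad_3d",
                     config = list(d = c(10, 60, 200), n_pde = c(100, 1000)),
                     run = function(cfg) {
                       geom <- dyad_geometry()
                       grid <- expand.grid(d = cfg$d, n_pde = cfg$n_pde)
                       res <- lapply(seq_len(nrow(grid)), function(i)
                         run_dyad(dyad_scenario(d = grid$d[i],
                                                n_pde = grid$n_pde[i],
                                                geometry = geom)))
                       data.frame(grid,
                                  conc_source = sapply(res, `[[`, "conc_source"),
                                  conc_shell = sapply(res, `[[`, "conc_shell"),
                                  conc_far = sapply(res, `[[`, "conc_far"),
                                  ratio = sapply(res, `[[`, "ratio"),
                                  drop = sapply(res, `[[`, "drop"),
                                  significant = sapply(res, `[[`, "significant"))
                     })
  )
  for (i in 1:5) {
    n <- 10^i
    p[[sprintf("fig3_%s", letters[i])]] <- particle_preset(300, n)
    p[[sprintf("fig4_%s", letters[i])]] <- particle_preset(10, n)
    p[[sprintf("s3_%s", letters[i])]] <- particle_preset(60, n)
  }
  p
}

#' Names of the available scenario presets
#' @return Character vector of preset names.
#' @export
preset_names <- function() sort(names(preset_registry()))

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  ## md5 of the canonical serialisation
  unname(tools::md5sum(f))
}

#' Run a named scenario preset
#'
#' Executes the scenario bound to `name` with optional configuration
#' overrides, under a fixed seed, and returns the result together with a run
#' record (preset, configuration hash, seed, package version, wall time).
#'
#' @param name preset name; see [preset_names()].
#' @param overrides named list of configuration overrides; unknown or
#'   type-mismatched keys are an error.
#' @param seed integer seed for the run's RNG.
#' @return List with `record` (class `run_record`) and `result`.
#' @examples
#' \donttest{
#' out <- run_preset("fig5")
#' attr(out$result$d300, "max_abs_delta")
#' }
#' @export
run_preset <- function(name, overrides = list(), seed = 1L) {
  reg <- preset_registry()
  if (!name %in% names(reg))
    stop("unknown preset '", name, "'; available: ",
         paste(sort(names(reg)), collapse = ", "))
  preset <- reg[[name]]
  cfg <- preset$config
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad))
      stop("unknown override(s): ", paste(bad, collapse = ", "))
    for (k in names(overrides)) {
      if (!is.numeric(overrides[[k]]) || !is.numeric(cfg[[k]]))
        stop("override '", k, "' must be numeric")
      cfg[[k]] <- overrides[[k]]
    }
  }
  set.seed(seed)
  t0 <- proc.time()[["elapsed"]]
  result <- preset$run(cfg)
  elapsed <- proc.time()[["elapsed"]] - t0
  record <- structure(list(preset = name, module = preset$module,
                           config = cfg, config_hash = config_hash(cfg),
                           seed = seed,
                           version = as.character(utils::packageVersion("campart")),
                           wall_time = elapsed),
                      class = "run_record")
  list(record = record, result = result)
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("run record: %s [%s] seed %d, hash %s, %.2f s (campart %s)\n",
              x$preset, x$module, x$seed, substr(x$config_hash, 1, 8),
              x$wall_time, x$version))
  invisible(x)
}

#' Compare analytic and stochastic compartmentation ratios
#'
#' Builds the comparison table across stochastic preset runs: analytic R
#' from the closed-form barrier model, fitted stochastic R with its
#' bootstrap standard error, and the z-score of the discrepancy.
#'
#' @param runs a list of outputs of [run_preset()] for stochastic presets
#'   (fig3/fig4/s3 family).
#' @return Data frame with one row per run; zero rows (with a warning) for
#'   empty input.
#' @export
summarize_runs <- function(runs) {
  if (!length(runs)) {
    warning("no runs to summarize")
    return(data.frame(preset = character(), d = numeric(),
                      n_pde = numeric(), analytic_r = numeric(),
                      stochastic_r = numeric(), se = numeric(),
                      z = numeric()))
  }
  rows <- lapply(runs, function(x) {
    if (is.null(x$result$estimate))
      stop("run '", x$record$preset, "' carries no stochastic R estimate")
    data.frame(preset = x$record$preset, d = x$record$config$d,
               n_pde = x$record$config$n_pde,
               analytic_r = x$result$analytic_r,
               stochastic_r = x$result$estimate$r,
               se = x$result$estimate$se, z = x$result$z)
  })
  do.call(rbind, rows)
}

#' All fifteen analytic compartmentation ratios
#'
#' The compartmentation ratio R = A/(A+B) of the 1D barrier model for every
#' combination of diffusion coefficient (300, 60, 10 um^2/s) and PDE count
#' (10^1..10^5 molecules, i.e. 4.1514e0..4.1514e4 uM averaged over the
#' pre-barrier region), the grid reported by the stochastic-model figures.
#'
#' @return Data frame with columns `d`, `n_pde`, `pde_tot`, `a`, `b`, `r`.
#' @export
analytic_r_table <- function() {
  grid <- expand.grid(d = c(300, 60, 10), n_pde = 10^(1:5))
  sol <- lapply(seq_len(nrow(grid)), function(i) {
    solve_steady_state(barrier_scenario(
      d = grid$d[i], pde_tot = pde_count_to_concentration(grid$n_pde[i])))
  })
  data.frame(grid, pde_tot = sapply(sol, function(s) s$scenario$pde_tot),
             a = sapply(sol, `[[`, "a"), b = sapply(sol, `[[`, "b"),
             r = sapply(sol, `[[`, "r"))
}
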