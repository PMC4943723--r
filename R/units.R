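## Shared unit system: lengths in micrometres, time in seconds, concentrations
## in micromolar.  The single conversion from molecule counts to uM happens
## through `uM_PER_MOLECULE_UM3` below; nothing else in the package converts
## units on its own.

#' Avogadro constant (molecules per mole)
#'
#' Fixed at the 2019 SI exact value.  Stated explicitly because several
#' published back-of-envelope molecule counts in this literature do not use a
#' consistent value; every conversion in this package goes through this
#' constant.
#'
#' @format A length-one numeric.
#' @export
AVOGADRO <- 6.02214076e23

## molecules per (uM * um^3): 6.02214076e23 * 1e-6 mol/L * 1e-15 L/um^3
MOLECULES_PER_UM_UM3 <- AVOGADRO * 1e-21

#' Kinetic constants of the cAMP-PDE reaction
#'
#' The bimolecular association of cAMP with a phosphodiesterase (PDE), its
#' dissociation, and the catalytic (hydrolysis) step:
#' cAMP + PDE <-> PDE.cAMP -> PDE, with rates `kf`, `kb`, `kcat`.
#' The derived Michaelis constant `km = (kb + kcat)/kf` is always computed,
#' never stored independently.
#'
#' Defaults: kf = 12 uM^-1 s^-1 (1.2e7 M^-1 s^-1), kb = 58.82 s^-1,
#' kcat = 14.70 s^-1, giving km ~ 6.1267 uM.
#'
#' @param kf association rate, per-uM per-second.
#' @param kb dissociation rate, per-second.
#' @param kcat catalytic rate, per-second.
#' @return An object of class `kinetic_constants`: list with `kf`, `kb`,
#'   `kcat` and the derived `km` (uM).
#' @examples
#' k <- kinetic_constants()
#' k$km  # ~6.1267
#' @export
kinetic_constants <- function(kf = 12, kb = 58.82, kcat = 14.70) {
  stopifnot(is.numeric(kf), is.numeric(kb), is.numeric(kcat),
            length(kf) == 1L, length(kb) == 1L, length(kcat) == 1L)
  if (kf <= 0 || kb <= 0 || kcat <= 0)
    stop("all kinetic rates must be > 0")
  structure(list(kf = kf, kb = kb, kcat = kcat, km = (kb + kcat) / kf),
            class = "kinetic_constants")
}

#' @export
print.kinetic_constants <- function(x, ...) {
  cat("cAMP-PDE kinetics: kf =", x$kf, "uM^-1 s^-1, kb =", x$kb,
      "s^-1, kcat =", x$kcat, "s^-1 (Km =", signif(x$km, 5), "uM)\n")
  invisible(x)
}

#' Convert a molecule count in a volume to a concentration
#'
#' @param n molecule count (>= 0).
#' @param volume volume in um^3 (> 0).
#' @return Concentration in uM.  1 uM corresponds to ~602.21 molecules/um^3.
#' @examples
#' molecules_to_concentration(10, 0.2 * 0.2 * 0.1)  # ~4.1514 uM
#' @export
molecules_to_concentration <- function(n, volume) {
  if (any(n < 0)) stop("molecule count must be >= 0")
  if (any(volume <= 0)) stop("volume must be > 0")
  n / (MOLECULES_PER_UM_UM3 * volume)
}

#' Convert a concentration in a volume to a molecule count
#'
#' Inverse of [molecules_to_concentration()]; the round trip is the identity
#' to well below 1 ppm.
#'
#' @param conc concentration in uM (>= 0).
#' @param volume volume in um^3 (> 0).
#' @return Expected molecule count (not rounded).
#' @export
concentration_to_molecules <- function(conc, volume) {
  if (any(conc < 0)) stop("concentration must be >= 0")
  if (any(volume <= 0)) stop("volume must be > 0")
  conc * MOLECULES_PER_UM_UM3 * volume
}

#' Convert a molecular source rate through a cross-section to an areal flux
#'
#' A membrane source emitting `rate` molecules per second across a
#' cross-sectional area is expressed as a flux in concentration x length /
#' time units, the natural boundary-condition unit of the one-dimensional
#' continuum model.
#'
#' @param rate molecules per second (>= 0).
#' @param cross_section area in um^2 (> 0).
#' @return Flux in uM um / s.
#' @examples
#' source_rate_to_flux(120, 0.2 * 0.2)  # ~4.982 uM um/s
#' @export
source_rate_to_flux <- function(rate, cross_section) {
  if (any(rate < 0)) stop("rate must be >= 0")
  if (any(cross_section <= 0)) stop("cross-section must be > 0")
  rate / (MOLECULES_PER_UM_UM3 * cross_section)
}

#' Write a flat parameter set to a YAML file
#'
#' Parameter sets (kinetics, signalling constants, scenario descriptors) are
#' plain named lists of scalars; they serialize to a flat YAML mapping.
#'
#' @param params a named list of numeric scalars (or an object such as
#'   [kinetic_constants()] that unclasses to one).
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  p <- unclass(params)
  if (is.null(names(p)) || any(names(p) == ""))
    stop("params must be a fully named list")
  yaml::write_yaml(p, path)
  invisible(path)
}

#' Read a flat parameter set from a YAML file
#'
#' @param path file path to read.
#' @return A named list.
#' @export
read_params <- function(path) {
  yaml::read_yaml(path)
}
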