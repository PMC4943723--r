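## beta1-adrenergic receptor -> Gs -> adenylyl cyclase signalling kinetics for
## the caveolar microdomains of the 2D sarcomere model.  Receptor/G-protein
## complexes are algebraic (fast equilibria); the three Gs species are ODEs.

#' Signalling parameters of the caveolar beta1AR/Gs/AC5-6/PDE cascade
#'
#' All concentrations in uM (isoproterenol `liso` is given in nM and converted
#' at the boundary), rates in 1/s or 1/(uM s).  Defaults are the published
#' caveolar-compartment constants for an adult ventricular myocyte.
#'
#' @param rb1_total total beta1-adrenergic receptor concentration, uM.
#' @param k_h,k_l high/low affinity ligand-receptor binding constants, uM.
#' @param k_c receptor-Gs binding constant, uM.
#' @param kact1,kact2 activation rate constants of the RGs and LRGs complexes,
#'   1/s.
#' @param khydr GTP hydrolysis rate constant of Gs-alpha-GTP, 1/s.
#' @param kreas re-association rate constant of Gs-alpha-GDP with
#'   Gs-beta-gamma, 1/(uM s).
#' @param gs_total total Gs protein, uM.
#' @param ac concentration of adenylyl cyclase 5/6, uM.
#' @param atp ATP concentration, uM.
#' @param km_atp AC5/6 Michaelis constant for ATP, uM.
#' @param af amplification factor for AC5/6 (mg purified protein per mg
#'   membrane protein).
#' @param mw_ac molecular weight of AC5/6, kDa.
#' @param pde2,pde3,pde4 caveolar PDE isoform concentrations, uM.
#' @param k_pde2,k_pde3,k_pde4 catalytic rate constants, 1/s.
#' @param km_pde2,km_pde3,km_pde4 Michaelis constants for cAMP, uM.
#' @param liso isoproterenol concentration, nM.
#' @return Object of class `signaling_params` (a named list).
#' @export
signaling_params <- function(rb1_total = 0.633,
                             k_h = 0.062, k_l = 0.567, k_c = 8.809,
                             kact1 = 0.1, kact2 = 5, khydr = 0.8,
                             kreas = 1.21e3,
                             gs_total = 10,
                             ac = 3.379, atp = 5e3, km_atp = 315,
                             af = 500, mw_ac = 130,
                             pde2 = 4.5, k_pde2 = 20, km_pde2 = 50,
                             pde3 = 5.6, k_pde3 = 1.25, km_pde3 = 0.08,
                             pde4 = 2.0, k_pde4 = 2.5, km_pde4 = 2.2,
                             liso = 30) {
  p <- as.list(environment())
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1L, logical(1))
  if (!all(num)) stop("all parameters must be numeric scalars")
  if (any(unlist(p) < 0)) stop("all parameters must be >= 0")
  structure(p, class = "signaling_params")
}

#' Gs-protein state of the caveolar cascade
#'
#' Dynamic species (uM); defaults are the published initial values.
#'
#' @param gsa_gtp active Gs-alpha-GTP.
#' @param gsa_gdp inactive Gs-alpha-GDP.
#' @param gs_bg free Gs-beta-gamma.
#' @return Object of class `gprotein_state`.
#' @export
gprotein_state <- function(gsa_gtp = 0.042, gsa_gdp = 0.0, gs_bg = 0.042) {
  if (any(c(gsa_gtp, gsa_gdp, gs_bg) < 0))
    stop("G-protein concentrations must be >= 0")
  structure(list(gsa_gtp = gsa_gtp, gsa_gdp = gsa_gdp, gs_bg = gs_bg),
            class = "gprotein_state")
}

#' Solve the receptor/G-protein fast-equilibrium algebra
#'
#' Free Gs follows from conservation (`gs_free = gs_total - gsa_gtp -
#' gsa_gdp`); the remaining unknown, free receptor, is the root of the
#' receptor-conservation equation coupling the RGs, LR and LRGs complex
#' equilibria.  The root is bracketed on `[0, rb1_total]` and solved to
#' machine tolerance.
#'
#' @param params a [signaling_params()].
#' @param state a [gprotein_state()].
#' @param liso isoproterenol concentration in nM (default: `params$liso`).
#' @return A list with `rb1_free`, `gs_free`, `rgs`, `lrb1`, `lrgs` (uM) and
#'   the conservation `residual`.
#' @export
solve_receptor_algebra <- function(params, state, liso = params$liso) {
  stopifnot(inherits(params, "signaling_params"),
            inherits(state, "gprotein_state"))
  l <- liso * 1e-3  # nM -> uM
  gs_free <- params$gs_total - state$gsa_gtp - state$gsa_gdp
  if (gs_free < 0)
    stop("active Gs species exceed gs_total; no free Gs available")
  rt <- params$rb1_total
  complexes <- function(rf) {
    rgs <- rf * gs_free / (gs_free + params$k_c)
    lrb1 <- l * (rf - rgs) / (l + params$k_l)
    lrgs <- if (l > 0) {
      lrb1 * (gs_free - rgs) /
        ((gs_free - rgs) + params$k_c * params$k_h / params$k_l) +
        l * rgs / (l + params$k_h)
    } else 0
    list(rgs = rgs, lrb1 = lrb1, lrgs = lrgs)
  }
  if (rt == 0) {
    return(list(rb1_free = 0, gs_free = gs_free, rgs = 0, lrb1 = 0, lrgs = 0,
                residual = 0))
  }
  f <- function(rf) {
    cx <- complexes(rf)
    rf + cx$lrb1 + cx$lrgs + cx$rgs - rt
  }
  sol <- stats::uniroot(f, c(0, rt), tol = .Machine$double.eps^0.75)
  rf <- sol$root
  cx <- complexes(rf)
  res <- f(rf)
  if (abs(res) > 1e-8)
    stop("receptor algebra did not converge; residual = ", res)
  list(rb1_free = rf, gs_free = gs_free, rgs = cx$rgs, lrb1 = cx$lrb1,
       lrgs = cx$lrgs, residual = res)
}

#' Advance the Gs-protein ODEs by one time step
#'
#' Semi-implicit (linearly implicit in each species' own consumption term)
#' update of Gs-alpha-GTP, Gs-alpha-GDP and Gs-beta-gamma:
#' activation of Gs by the RGs and LRGs complexes, hydrolysis of
#' Gs-alpha-GTP, and re-association of Gs-alpha-GDP with Gs-beta-gamma.
#' If a step would drive any species negative it is rejected and retried as
#' two half steps.
#'
#' @param state a [gprotein_state()].
#' @param params a [signaling_params()].
#' @param dt time step, s (> 0).
#' @param liso isoproterenol, nM.
#' @param algebra optional pre-computed result of [solve_receptor_algebra()].
#' @return Updated `gprotein_state`.
#' @export
step_gprotein <- function(state, params, dt, liso = params$liso,
                          algebra = NULL) {
  stopifnot(dt > 0)
  if (is.null(algebra))
    algebra <- solve_receptor_algebra(params, state, liso)
  act <- algebra$lrgs * params$kact2 + algebra$rgs * params$kact1
  gtp <- (state$gsa_gtp + dt * act) / (1 + dt * params$khydr)
  gdp <- (state$gsa_gdp + dt * params$khydr * gtp) /
    (1 + dt * params$kreas * state$gs_bg)
  bg <- (state$gs_bg + dt * act) / (1 + dt * params$kreas * gdp)
  if (min(gtp, gdp, bg) < 0) {
    half <- step_gprotein(state, params, dt / 2, liso)
    return(step_gprotein(half, params, dt / 2, liso))
  }
  gprotein_state(gsa_gtp = gtp, gsa_gdp = gdp, gs_bg = bg)
}

#' Raw AC5/6 activation factor
#'
#' Hill-type dependence of the AC5/6 turnover on active Gs-alpha-GTP with a
#' basal offset of 0.7, times the molecular-weight factor; dimensionless up to
#' the published unit conventions.
#' @noRd
ac_activation <- function(params, gsa_gtp) {
  g <- gsa_gtp^0.9787
  (0.7 + 3.8234 * g / (0.1986 + g)) * params$mw_ac / 60e-3
}

#' AC5/6 cAMP production rate
#'
#' Hill-type activation by Gs-alpha-GTP times ATP saturation.  The published
#' functional form is dimensionally ambiguous, so a single explicit
#' normalisation constant `ac_scale` multiplies it; [calibrate_ac_scale()]
#' chooses it so that basal production balances basal degradation at 0.1 uM
#' cAMP.  The constant is always surfaced, never hidden.
#'
#' @param params a [signaling_params()].
#' @param gsa_gtp active Gs-alpha-GTP, uM (>= 0).
#' @param ac_scale normalisation constant (default 1: raw published form).
#' @return Production rate, uM/s.
#' @export
ac_production_rate <- function(params, gsa_gtp, ac_scale = 1) {
  if (any(gsa_gtp < 0)) stop("gsa_gtp must be >= 0")
  ac_scale * ac_activation(params, gsa_gtp) * (params$ac / params$af) *
    params$atp / (params$km_atp + params$atp)
}

#' Calibrate the AC5/6 normalisation constant
#'
#' Returns the `ac_scale` for which basal production (at the initial
#' Gs-alpha-GTP of `state`) equals basal PDE degradation at `camp_basal`,
#' with unscaled (1x) PDE concentrations.
#'
#' @param params a [signaling_params()].
#' @param state a [gprotein_state()] defining the basal operating point.
#' @param camp_basal basal cAMP, uM.
#' @return The scalar `ac_scale`.
#' @export
calibrate_ac_scale <- function(params, state = gprotein_state(),
                               camp_basal = 0.1) {
  basal_deg <- pde_degradation_rate(params, camp_basal)
  raw <- ac_production_rate(params, state$gsa_gtp, ac_scale = 1)
  basal_deg / raw
}

#' Total PDE degradation rate (isoforms 2, 3, 4)
#'
#' Sum over isoforms of `k_PDEx * PDEx * cAMP / (Km_PDEx + cAMP)`; linear in
#' the PDE concentrations, so `pde_scale` implements the "n-fold PDE"
#' scenarios exactly.
#'
#' @param params a [signaling_params()].
#' @param camp cAMP concentration(s), uM (>= 0).
#' @param pde_scale multiplier on all PDE concentrations (default 1).
#' @return Degradation rate(s), uM/s.
#' @examples
#' pde_degradation_rate(signaling_params(), 0.1)  # ~4.286 uM/s
#' @export
pde_degradation_rate <- function(params, camp, pde_scale = 1) {
  if (any(camp < 0)) stop("camp must be >= 0")
  pde_scale * (params$k_pde2 * params$pde2 * camp / (params$km_pde2 + camp) +
               params$k_pde3 * params$pde3 * camp / (params$km_pde3 + camp) +
               params$k_pde4 * params$pde4 * camp / (params$km_pde4 + camp))
}
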