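---
title: "Methods: modelling subcellular cAMP compartmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling subcellular cAMP compartmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(campart)
```

# The scientific question

Cyclic AMP (cAMP) is a small, rapidly diffusing second messenger, yet
receptor-specific cAMP responses in cardiac myocytes behave as if the
messenger were confined to sub-micron domains.  Two candidate mechanisms
dominate the literature: *functional barriers* — layers of phosphodiesterase
(PDE) that hydrolyse cAMP on its way out of a production domain — and
*anatomical barriers* — the crowded geometry of the dyadic cleft between
t-tubule and junctional sarcoplasmic reticulum, flanked by mitochondria.
`campart` implements a hierarchy of four models, sharing one unit system
(µm, s, µM) and one set of cAMP–PDE kinetic constants, that interrogate
these mechanisms quantitatively.

All parameters are inputs printed in the source literature; there are no
external data files.  The package's internal unit conversion fixes the
Avogadro constant at its exact SI value, 6.02214076e23.  (One published
back-of-envelope count, "~1.3 × 10⁶ PDE molecules per cell" from 0.1 µM in
31,400 µm³, is inconsistent with any Avogadro constant — direct arithmetic
gives ≈ 1.9 × 10⁶ — and is deliberately not reproduced anywhere in this
package.)

# Tier 1: the closed-form functional-barrier model

A membrane at $z = 0$ injects cAMP at areal flux $J_B$ (µM·µm/s) into a
column of length $L$; all PDE sits in a plane at $z = L^*$, with total
concentration $\mathrm{PDE}_{tot}$ averaged over $0 \le z \le L^*$.  cAMP
binds PDE at rate $k_f$, unbinds at $k_b$, and is hydrolysed at $k_{cat}$,
giving a Michaelis constant $K_m = (k_b + k_{cat})/k_f \approx 6.13$ µM.
At steady state the barrier must hydrolyse exactly the injected flux,

$$J_B = k_{cat}\,(\mathrm{PDE}_{tot} L^*)\,\frac{B}{K_m + B},$$

which yields the plateau behind the barrier,
$B = K_m J_B / (k_{cat}\,\mathrm{PDE}_{tot} L^* - J_B)$, while the diffusive
transport of that flux to the barrier sets the linear drop
$A = J_B L^* / D$.  The concentration profile is linear from $A+B$ at the
membrane down to $B$ at the barrier, and flat beyond; the
**compartmentation ratio** $R = A/(A+B)$ is 0 for a uniform column and 1
for complete trapping.  A bounded steady state requires the areal catalytic
capacity to exceed the influx ($k_{cat}\mathrm{PDE}_{tot}L^* > J_B$);
`solve_steady_state()` raises an explicit error otherwise, and the
sensitivity sweep reports such grid points as `NA` rather than failing.

Two unit conventions matter and are derived, never typed in: the influx for
120 molecules/s over the 0.2 × 0.2 µm cross-section (≈ 4.982 µM·µm/s) and
the barrier concentration for $n$ molecules averaged over the pre-barrier
volume (10 molecules ≈ 4.1514 µM).  Using the exactly derived values (not
their 4–5 digit printed roundings) is what reproduces the published $R$
values to four significant figures:

```{r analytic}
head(analytic_r_table(), 3)
```

## Parameter sensitivity

`sensitivity_sweep()` perturbs the composite $D/(k_f L^*)$, $k_b$,
$k_{cat}$ and $J_B$ by ±20% and tabulates $R$ over a PDE grid.  The
composite is perturbed through $D$ alone: scaling $k_f$ or $L^*$ instead
would also change $K_m$ and the areal $V_{max}$ — physically different
experiments that demonstrably break the insensitivity pattern.  Over the
five published barrier concentrations and all three diffusion constants the
largest |ΔR| the package computes is ≈ 0.056, and the production-rate arm
is everywhere within 5 × 10⁻³ of the unperturbed curve.

# Tier 2: the 2D sarcomeric-space model

The space between adjacent t-tubules is a 2 × 10 µm rectangle with no-flux
boundaries.  Each 10-µm membrane edge carries 50 caveolar domains (0.1 µm
along the edge × 0.01 µm deep, alternating with 0.1 µm extracaveolar gaps;
the masks tile the edge exactly).  Caveolar cells carry the full signalling
cascade; extracaveolar cells are labelled but parameter-identical to bulk,
since no simulated scenario distinguishes them.

The cascade has three layers:

* **Receptor algebra** (fast equilibria).  Free Gs follows from
  conservation; the single remaining unknown, free β₁-receptor, is the
  bracketed root of the receptor-conservation equation coupling the RGs,
  ligand-receptor and ligand-receptor-Gs complexes.  A dense grid scan of
  the conservation residual validates the root in the test suite.
* **G-protein ODEs** for Gs-α-GTP, Gs-α-GDP and Gs-βγ: activation by the
  RGs/LRGs complexes, hydrolysis, re-association.  The update is
  semi-implicit in each species' own consumption term (the re-association
  rate constant, 1210 µM⁻¹s⁻¹, makes a fully explicit update stiff); a
  step that would go negative is halved and retried.
* **AC5/6 production and PDE2/3/4 degradation**, Hill-type and
  Michaelis–Menten respectively.  The published AC5/6 functional form is
  dimensionally ambiguous (a molecular-weight over minutes factor and an
  amplification factor whose units do not reduce), so the package keeps the
  printed form and multiplies it by one explicit normalisation constant,
  `ac_scale`, calibrated once so that basal production balances basal
  degradation at 0.1 µM cAMP with the published parameter set
  (`calibrate_ac_scale()` ≈ 0.2214).  The constant is an argument of every
  simulation function, never hidden.

**Numerics.**  Reactions are applied explicitly, then diffusion advances by
one fully implicit backward-Euler step at the reference dt = 0.001 s on a
conservative finite-volume grid, graded in the depth direction (0.01 µm
cells within 0.05 µm of each membrane, 0.05 µm in the bulk; 0.05 µm along
the membrane).  The implicit matrix is factored once per run (sparse
Cholesky), so each step is a pair of triangular solves.  Backward Euler was
chosen as the default because its operator is an M-matrix — the step is
monotone and positivity-preserving.  A Peaceman–Rachford ADI scheme is
available (`method = "adi"`); on smooth fields the two schemes agree to
1 part in 10⁴, but on the sharp caveolar/bulk contrast of the washout
scenario the ADI split carries an $O(\Delta t^2)$ artifact localised in the
10-nm reactive layer, so it is the alternative, not the default.  Mass is
conserved to 10⁻¹⁰ relative per step by construction; a mirror-symmetric
initial state stays symmetric to solver precision.

**Scenarios.**  `run_scenario_stimulation()` applies 30 nM isoproterenol
from basal 0.1 µM cAMP with the caveolar PDE concentrations scaled by 0, 1
or 10, and classifies each snapshot with the 15% rule (significant when the
domain minimum falls more than 15% below the production-site mean) plus a
PKA-relevance flag (any compartment mean above 1 µM).
`run_scenario_washout()` starts from the experimentally motivated basal
contrast (bulk 1.0 µM, caveolar 0.1 µM) with 10-fold PDEs and **no receptor
stimulation**: the ligand concentration is zero but the basal, unstimulated
AC turnover remains active.  This reading ("no stimulation", rather than
"no production at all") is deliberate: with production fully disabled the
decline time of both compartments to 0.1 µM converges to 2.41 s, with the
basal turnover retained it converges to 2.55 s, against a published value
of ≈ 2.5 s.  "Reaches the bulk level" is evaluated at whole time steps,
within 1% of the bulk mean, because the published equilibration times are
single time steps.

One caveat the tests record honestly: starting the 10×-PDE scenarios from
the 1×-balanced basal state creates a genuine production/degradation
imbalance whose relaxation transient carries maximum spatial gradients of a
few nM during the first ~0.5–1 s at D = 10–60 µm²/s (decaying to well below
1 nM afterwards).  The *classification* is "no significant gradient" for
every panel at every time; the sub-nanomolar statement holds throughout
only for the D = 300 µm²/s panels.

# Tier 3: the stochastic barrier model

A 0.2 × 0.2 × 1.0 µm reflective box; a 0.1 × 0.1 µm caveolar patch on the
$z=0$ face emits cAMP as a pooled Poisson source at 120 molecules/s (15
receptors × 8 molecules/s — indistinguishable from independent emitters in
any reported observable); PDE sites sit on the plane $z = 0.1$ µm at the
published surface densities (`surface_grid_density()`).  Particles take
isotropic Gaussian steps of per-axis variance $2D\Delta t$.

The binding machinery is **calibrated to the macroscopic rate** rather than
copied from any particular simulator's internals.  A particle whose step
straddles the plane is tested against the site occupying the lattice cell
under the crossing point, within capture radius $r_c = (\pi\sigma)^{-1/2}$
(each capture disc has area $1/\sigma$); it binds with probability

$$p = \frac{k_f\,\sigma}{2\,N_c}\sqrt{\frac{\pi\,\Delta t}{D}} \Big/ c_f,$$

where $N_c$ converts µM·µm³ to molecules and $c_f$ is the (deterministic,
quadrature-computed) fraction of a lattice cell covered by its capture
disc.  This is derived from the one-sided diffusive crossing flux
$C\sqrt{D\Delta t/\pi}$ and makes the well-mixed association rate equal
$k_f[\mathrm{cAMP}][\mathrm{PDE}]$ — the correctness contract, verified to
5% by `validate_binding_rate()`.  The probability grows as
$\sqrt{\Delta t}$, so `admissible_dt()` bounds the usable step; the
published operating point ($\Delta t = 5\times10^{-9}$ s) is admissible at
every tabulated density.  Bound sites release (at $k_b$, the particle
re-appearing one diffusive step off the plane, side chosen uniformly — a
choice the steady state is insensitive to) or hydrolyse (at $k_{cat}$) as
competing exponential events.  Particle bookkeeping
(produced = degraded + free + bound) is exact at every frame, and runs are
bit-reproducible given a seed.

The default desk-scale step is $\Delta t = 10^{-6}$ s with the calibrated
probability, and the reference runs simulate 3 s, averaging z-profiles over
the final 2 s — a scaled-down stand-in for the published 10-s runs whose
full-fidelity time step is not desk-feasible.  A convergence check in the
acceptance suite verifies that estimates at $\Delta t = 10^{-6}$ and
$10^{-7}$ s agree within their joint Monte-Carlo error.
`estimate_r()` fits the piecewise analytic profile shape (linear to the
barrier, flat beyond) to the frame-averaged z-histogram by least squares
and bootstraps frames for a standard error; fits with a non-positive
plateau are flagged as degenerate.

# Tier 4: the dyadic-cleft anatomical model

A parametric voxel geometry stands in for segmented electron-tomography
anatomy: a cleft of ≈ 1040 × 765 × 415 nm (snapped to whole 25-nm voxels)
framed by impermeable blocks — t-tubule below, junctional SR above, two
mitochondria flanking — and opening into surrounding cytosol along the
remaining faces, with 1 µm of cytosol padding per axis (a config knob; the
qualitative classification is insensitive to it because the far level is
set by flux balance, see below).  Fifteen AC molecules emit 120 molecules/s
— the emission rate inherited from the stochastic model, as the anatomical
scenarios state only the molecule count — from a 50 × 25 × 25 nm box at the
cleft centre, snapped to its own dimensions so refined grids reproduce the
identical physical region.  A hollow PDE sphere (outer diameter 200 nm,
thickness 25 nm; the compact 25-nm-radius variant is a config option)
surrounds the source, its concentration derived from the molecule count and
the voxelised shell volume.

The steady state of $D\nabla^2 c - V_{max}\,c/(K_m + c) + s = 0$ is found
by Picard iteration on the Michaelis–Menten denominator, each linearised
system solved by Jacobi-preconditioned conjugate gradients on the
matrix-free 7-point stencil (obstacle faces carry identically zero flux by
construction).  Concentrations here sit far below $K_m$, so Picard
converges in a handful of iterations; at convergence total shell
degradation balances total source influx to 0.1%.  The solver is
deterministic: identical scenarios give bit-identical fields.

Reported metrics: the production-site mean, the mean inside the shell
interior, the far-cytosol mean (outside the obstacle frame), and the 15%
classifier relative to the production site.  Two honest subtleties:

* The production-site mean of a compact source is a near-singular
  observable; grid-refinement stability is therefore asserted on the
  *inside-shell/far-cytosol* ratio, which is well resolved (< 5% change
  from 25 to 12.5 nm voxels).
* In a closed (no-flux) domain at steady state, *all* production is
  absorbed by the shell, so the far-cytosol level is pinned at the shell's
  absorption balance, $c \approx S(K_m + c)/(k_{cat}[\mathrm{PDE}]
  V_{shell})$, regardless of the obstacles; `obstacle_effect()`
  consequently measures a near-zero (non-negative within solver tolerance)
  change in the steady-state relative drop.  Anatomy matters for transients
  and for open cellular contexts, which are outside this model's scope.

The same flux-balance argument explains the one qualitative cell where the
15% rule disagrees with the published reading: the far level scales as
$1/n_{PDE}$ while the near-source excess scales as $1/D$ and is independent
of $n_{PDE}$, so at (D = 60 µm²/s, 1000 PDEs) the *relative* drop is ≈ 30%
even though the *absolute* excess (≈ 0.02 µM) is minuscule.  The published
pattern — compartmentation iff D = 10 µm²/s, independent of PDE count —
tracks the absolute excess; the 15% relative rule reproduces it in five of
six cells, and the acceptance suite leaves the sixth red rather than
redefining the rule.

# Problem sizes and reproducibility

The reference configurations used by the tests and the acceptance script
are: the full 2 × 10 µm graded mesh (9,600 cells) at dt = 0.001 s for the
2D scenarios; 3-s stochastic runs (1-ms frames, final 2 s averaged) at
$\Delta t = 10^{-6}$ s; and the full 130 × 111 × 105 voxel dyad at 25-nm
spacing.  Module-level tests exercise reduced-padding dyad geometries and
shorter windows.  All stochastic code draws from R's RNG, so `set.seed()`
makes any run reproducible; scenario presets (`run_preset()`) record the
seed, configuration hash and package version with every run.

# Known limitations

* The 2D extracaveolar domains are labelled but carry no distinct
  parameters; no simulated scenario distinguishes them from bulk.
* The washout interpretation (basal AC turnover retained at zero ligand) is
  a documented reading of an ambiguous protocol; both variants are
  available and both converge under mesh and time-step refinement.
* The dyad model is an idealisation: axis-aligned obstacles, a voxelised
  shell, and a closed domain.  Its claims are about steady-state fields;
  transient anatomical effects are out of scope.
* PKA-mediated buffering of cAMP is represented only through the reduced
  effective diffusion coefficient (10 µm²/s), not as explicit binding
  reactions.
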