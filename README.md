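# campart

Models of subcellular cAMP compartmentation in cardiac myocytes.

Cyclic AMP (cAMP) regulates many cellular functions through receptor-specific,
spatially confined responses, yet it is a small, fast-diffusing messenger.
`campart` implements a hierarchy of models that test whether localized
phosphodiesterase (PDE) activity — a "functional barrier" — and anatomical
obstacles in the dyadic cleft can produce sub-micron cAMP gradients:

1. **Closed-form 1D barrier model.** A membrane injects cAMP at areal flux
   J_B; a PDE plane at depth L\* hydrolyses it with Michaelis–Menten kinetics
   (Km = (kb + kcat)/kf ≈ 6.13 µM).  The steady state has a linear drop
   A = J_B·L\*/D in front of the barrier and a plateau
   B = Km·J_B/(kcat·PDE_tot·L\* − J_B) behind it.  The **compartmentation
   ratio** R = A/(A+B) measures trapping: 0 = uniform, 1 = fully trapped.
2. **2D continuum sarcomeric-space model** (2 × 10 µm between t-tubules) with
   β1-adrenergic receptor → Gs → adenylyl-cyclase production and PDE2/3/4
   degradation confined to 100 caveolar microdomains, solved by a
   conservative implicit finite-volume scheme.
3. **3D stochastic Brownian-particle model** of a single caveolar source and
   a PDE barrier plane in a 200 × 200 × 1000 nm box, with binding
   probabilities calibrated to recover the macroscopic association rate.
4. **3D continuum dyadic-cleft model** with impermeable t-tubule/SR/
   mitochondria obstacles, an AC point source and a hollow PDE sphere,
   solved to steady state by conjugate gradients.

## Worked example

The analytic barrier model at D = 10 µm²/s with 100 PDE molecules on the
barrier plane (≈ 41.5 µM averaged over the pre-barrier region):

```r
library(campart)
sc <- barrier_scenario(d = 10, pde_tot = pde_count_to_concentration(100))
solve_steady_state(sc)
#> 1D barrier steady state: A = 0.04982 uM, B = 0.5446 uM, R = 0.08381
```

A + B ≈ 0.594 µM is the concentration at the membrane, B ≈ 0.545 µM the
plateau beyond the barrier, and R ≈ 0.084 says that even at this density the
barrier holds back only ~8% of the cAMP.  The stochastic model run under the
same conditions agrees within its Monte-Carlo error:

```r
set.seed(1)
ps <- particle_scenario(d = 10, n_pde = 100, dt = 1e-6, duration = 3,
                        frame_interval = 1e-3)
run <- run_particle(ps)
run
#> particle run: produced 330, degraded 310, free 14, bound 6 (3000 frames)
est <- estimate_r(z_profile(run, window = c(1, Inf)))
#> stochastic R = 0.1236 +/- 0.032
```

The bookkeeping line is exact by construction (330 = 310 + 14 + 6).  The 2D
washout scenario — bulk pre-loaded to 1.0 µM, caveolae at 0.1 µM, ten-fold
PDEs, no receptor stimulation — returns to basal in about two and a half
seconds at D = 10 µm²/s:

```r
run_scenario_washout(d = 10)$decline_time
#> [1] 2.554
```

Scenario presets mirroring the study figures are registered under
`preset_names()` and run with `run_preset("fig4_b")` etc.;
`summarize_runs()` tabulates analytic vs stochastic R with z-scores, and
`analytic_r_table()` prints all fifteen analytic ratios.

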