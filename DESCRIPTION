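Package: campart
Title: Models of Subcellular cAMP Compartmentation in Cardiac Myocytes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A hierarchy of models of cyclic AMP (cAMP) compartmentation in the
    subcellular space of a cardiac ventricular myocyte: a closed-form
    one-dimensional steady-state model of a phosphodiesterase (PDE) "functional
    barrier" with its compartmentation ratio R and parameter-sensitivity sweep;
    a two-dimensional continuum reaction-diffusion model of the inter-t-tubule
    sarcomeric space with beta1-adrenergic receptor, G-protein and adenylyl
    cyclase kinetics in caveolar microdomains; a three-dimensional stochastic
    Brownian-particle simulation of cAMP production, diffusion and degradation
    at a PDE barrier plane; and a three-dimensional continuum model of a dyadic
    cleft with impermeable anatomical obstacles. Includes shared unit
    conversions, scenario presets, and tools to compare stochastic and analytic
    compartmentation estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
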