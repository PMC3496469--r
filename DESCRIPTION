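Package: nnlifpd
Title: Population-Density Analysis of Nonlinear Noisy Leaky Integrate-and-Fire Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solves the Fokker-Planck (population-density) formulation of the
    nonlinear noisy leaky integrate-and-fire neuron network model, in which the
    drift and diffusion of the membrane-voltage density are coupled to the
    network's own mean firing rate through the probability flux at the firing
    threshold.  Provides positivity-preserving explicit finite-difference
    solvers (first-order upwind, fifth-order WENO, and Chang-Cooper flux
    discretisations with TVD Runge-Kutta time stepping), enumeration and
    classification of stationary firing rates from the implicit steady-state
    condition, sufficient-condition certificates for finite-time blow-up of
    the firing rate based on exponential moments of the initial density,
    a-priori moment-bound checks, and relative-entropy diagnostics for the
    relaxation of the uncoupled (linear) model towards its unique equilibrium.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    generics,
    ggplot2,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    dplyr,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
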