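Package: reachsim
Title: Stochastic Simulation and Analytic Theory of Tethered Membrane Signaling Reactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Particle-based lattice stochastic simulation (a convergent
    reaction-diffusion master equation sampler) and analytic tools for
    membrane-confined tethered signaling reactions, in which enzymes anchored
    to receptors diffusing in the plasma membrane act on substrates through a
    Gaussian "molecular reach" interaction kernel derived from the worm-like
    chain polymer model.  Includes worm-like-chain reach arithmetic, 3D and
    idealized 2D interaction kernels, moment-matched Doi (volume-reactivity)
    calibration, exact and asymptotic two-particle mean-reaction-time theory
    on discs and spheres, receptor signaling models (PD-1 dephosphorylating
    CD28; kinase-phosphatase push-pull), steady-state dose-response sweeps and
    IC50/EC50 potency extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
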