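## Named micro-scenarios with machine-checkable expected properties.
## Each fixture runs end-to-end in well under a minute and is used by the
## test suite; the expected values come from independent closed forms.

#' Generate a named test fixture
#'
#' Available fixtures:
#' \describe{
#' \item{"static-pair"}{Two immobile molecules at a fixed separation with a
#'   Gaussian-kernel rule; the reaction time is exactly
#'   Exponential(`kcat * sigma(r; L)`), and `expected$mean_time` gives its
#'   mean.}
#' \item{"hill-curve"}{Synthetic inhibitor dose-response
#'   `f(c) = 1/(1 + c/c0)` with `c0 = 10` and additive Gaussian noise
#'   (sd 0.01) on a 9-point log grid; `expected$ic50 = 10`.}
#' \item{"doi-two-particle"}{One fixed and one diffusing molecule on a
#'   reflecting 300 nm square with the moment-matched indicator kernel
#'   (L = 8.5 nm, kcat = 0.1/uM/s, D = 0.1 um^2/s); `expected$mean_time`
#'   is the analytic well-mixed mean reaction time on the equal-area disc.}
#' \item{"pushpull-micro"}{A 9-substrate push-pull world (published-table
#'   concentrations, fast diffusion) for conservation and smoke checks;
#'   `expected$n_substrate = 9`, `expected$mf_fraction` is the mean-field
#'   stationary fraction.}
#' }
#'
#' @param name Fixture name.
#' @param seed Integer seed used for any randomness in the fixture inputs.
#' @return List with `name`, runnable ingredients (fixture-specific:
#'   `domain`/`network`/`world`, a `model`, or data vectors) and an
#'   `expected` list of machine-checkable properties.
#' @export
#' @examples
#' fx <- generate_fixture("static-pair", seed = 1)
#' fx$expected$mean_time
generate_fixture <- function(name, seed = 1) {
  switch(name,
    "static-pair" = {
      dom <- lattice_domain(2, 300, 128)
      kern <- reach_kernel(8.5, convert_catalytic_3d(0.1))
      net <- reaction_network(
        list(species_def("A", 0, 0), species_def("B", 0, 0),
             species_def("Bp", 0, 0)),
        pairwise = list(pairwise_rule("A", "B", "A", "Bp", kern)))
      sep_vox <- 3L
      r <- sep_vox * dom$spacing
      world <- build_world(dom, net, seed = seed,
                           counts = c(A = 1, B = 1, Bp = 0),
                           positions = list(A = matrix(c(10L, 10L), 1),
                                            B = matrix(c(10L + sep_vox, 10L), 1)))
      list(name = name, domain = dom, network = net, world = world,
           separation = r,
           expected = list(rate = kernel_propensity(kern, r),
                           mean_time = 1 / kernel_propensity(kern, r)))
    },
    "hill-curve" = {
      set.seed(seed)
      c0 <- 10
      conc <- 10^seq(log10(c0 / 30), log10(c0 * 30), length.out = 9)
      fraction <- 1 / (1 + conc / c0) + stats::rnorm(length(conc), 0, 0.01)
      list(name = name, concentration = conc, fraction = fraction,
           noise_sd = 0.01,
           expected = list(ic50 = c0))
    },
    "doi-two-particle" = {
      L <- 8.5; Dum <- 0.1
      cal <- calibrate_doi(reach_kernel(L, convert_catalytic_3d(0.1)))
      dom <- lattice_domain(2, 300, 128, boundary = "reflecting")
      net <- reaction_network(
        list(species_def("A", 0, 0), species_def("B", Dum, 0),
             species_def("X", 0, 0)),
        pairwise = list(pairwise_rule("A", "B", "A", "X", cal)))
      ctr <- matrix(rep(dom$voxels_per_axis %/% 2L, 2), 1)
      world <- build_world(dom, net, seed = seed,
                           counts = c(A = 1, B = 1, X = 0),
                           positions = list(A = ctr))
      list(name = name, domain = dom, network = net, world = world,
           calibration = cal,
           expected = list(
             mean_time = mrt_wellmixed("2.5D", convert_catalytic_3d(0.1),
                                       L, Dum)$T))
    },
    "pushpull-micro" = {
      m <- pushpull_model(E = 150, D_S = 0.1, D_E = 0.1, L_e = 10)
      list(name = name, model = m,
           expected = list(n_substrate = 9,
                           mf_fraction = mean_field(m)$p0))
    },
    stop("unknown fixture: ", name)
  )
}
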