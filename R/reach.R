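## Molecular-reach arithmetic and tethered-interaction kernels.
##
## All lengths are in nm, times in s.  Catalytic efficiencies are volume-rates
## (nm^3/s) for 3D kernels and area-rates (nm^2/s) for 2D kernels, so that
## kcat * sigma(r) always has units 1/s.

#' Avogadro-number convention used for unit conversions
#'
#' The package converts catalytic efficiencies quoted in molar units
#' (\eqn{\mu M^{-1} s^{-1}}) to per-molecule volume rates (nm\eqn{^3} s\eqn{^{-1}})
#' using the rounded Avogadro constant 6.023e23 mol\eqn{^{-1}}.  This
#' (historical) rounding is retained deliberately: it reproduces published
#' two-dimensional rate conversions such as 221.3736 nm\eqn{^2} s\eqn{^{-1}}
#' to five significant figures.  Pass a different value to the conversion
#' functions to use another convention.
#'
#' @return The default Avogadro constant, in mol^-1.
#' @export
#' @examples
#' reach_avogadro()
reach_avogadro <- function() 6.023e23

#' Contour length of an unstructured peptide chain
#'
#' @param residue_count Number of amino acids between the membrane anchor and
#'   the reactive site.
#' @param bond_length C-alpha to C-alpha bond length in nm (default 0.4).
#' @return Contour length in nm.
#' @export
#' @examples
#' contour_length(11) # CD28 membrane-to-YMNM segment: 4.4 nm
contour_length <- function(residue_count, bond_length = 0.4) {
  if (any(residue_count < 0)) stop("residue_count must be >= 0")
  if (any(bond_length <= 0)) stop("bond_length must be > 0")
  bond_length * residue_count
}

#' Worm-like chain reach parameter
#'
#' The reach of a single flexible component is \eqn{\sqrt{l_p l_c}}, the
#' root-mean-square scale over which a worm-like chain of persistence length
#' \eqn{l_p} and contour length \eqn{l_c} explores space.
#'
#' @param persistence_length Persistence length in nm (0.4 nm for unstructured
#'   polypeptide).
#' @param contour_length Contour length in nm.
#' @return Reach in nm.
#' @export
#' @examples
#' wlc_reach(0.4, contour_length(11)) # ~1.3 nm
wlc_reach <- function(persistence_length, contour_length) {
  if (any(persistence_length < 0) || any(contour_length < 0)) {
    stop("persistence_length and contour_length must be >= 0")
  }
  sqrt(persistence_length * contour_length)
}

#' Worm-like chain component of a tethered reaction
#'
#' Convenience constructor bundling the residue count, persistence length and
#' derived contour length / reach of one reaction component (a receptor tail
#' or a tethered enzyme).
#'
#' @inheritParams contour_length
#' @inheritParams wlc_reach
#' @return A list of class `wlc_component` with fields `residue_count`,
#'   `persistence_length`, `bond_length`, `contour_length` and `reach` (nm).
#' @export
#' @examples
#' wlc_component(56) # PD-1 tail, reach ~3.0 nm
wlc_component <- function(residue_count, persistence_length = 0.4,
                          bond_length = 0.4) {
  lc <- contour_length(residue_count, bond_length)
  structure(list(
    residue_count = residue_count,
    persistence_length = persistence_length,
    bond_length = bond_length,
    contour_length = lc,
    reach = wlc_reach(persistence_length, lc)
  ), class = "wlc_component")
}

#' @export
print.wlc_component <- function(x, ...) {
  cat(sprintf("WLC component: N = %d residues, l_p = %g nm, l_c = %g nm, reach = %.2f nm\n",
              x$residue_count, x$persistence_length, x$contour_length, x$reach))
  invisible(x)
}

#' Combined molecular reach of a reaction
#'
#' Component reaches add in quadrature: the reach of the full reaction is the
#' square root of the sum of squared component reaches.
#'
#' @param components Numeric vector of component reaches in nm, or a list of
#'   [wlc_component] objects / numbers.
#' @return Combined reach in nm.
#' @export
#' @examples
#' combined_reach(c(3.0, 7.9, 1.3)) # PD-1 + SHP-2 + CD28: ~8.5 nm
combined_reach <- function(components) {
  if (is.list(components)) {
    components <- vapply(components, function(x) {
      if (inherits(x, "wlc_component")) x$reach else as.numeric(x)
    }, numeric(1))
  }
  if (length(components) == 0) stop("components must be non-empty")
  if (any(components < 0)) stop("component reaches must be >= 0")
  sqrt(sum(components^2))
}

#' Gaussian tethered-interaction kernels
#'
#' `sigma3d()` is the probability density (nm^-3) that the two reactive sites
#' of a tethered enzyme/substrate pair are in contact in the volume proximal
#' to the membrane, given membrane-anchor separation `r`; it integrates to one
#' over 3D space.  `sigma2d()` is the idealized planar kernel (nm^-2) that
#' forces contact within the membrane plane; it integrates to one over the
#' plane.  `L` is the molecular reach of the reaction.
#'
#' @param r Anchor separation(s) in nm.
#' @param L Molecular reach in nm (> 0).
#' @return Density values, nm^-3 (`sigma3d`) or nm^-2 (`sigma2d`).
#' @export
#' @examples
#' sigma3d(0, 8.5)
#' integrate(function(r) sigma3d(r, 8.5) * 4 * pi * r^2, 0, Inf)$value # ~1
sigma3d <- function(r, L) {
  if (any(L <= 0)) stop("L must be > 0")
  if (any(r < 0)) stop("r must be >= 0")
  (3 / (2 * pi * L^2))^1.5 * exp(-3 * r^2 / (2 * L^2))
}

#' @rdname sigma3d
#' @export
sigma2d <- function(r, L) {
  if (any(L <= 0)) stop("L must be > 0")
  if (any(r < 0)) stop("r must be >= 0")
  (3 / (2 * pi * L^2)) * exp(-3 * r^2 / (2 * L^2))
}

#' Convert catalytic efficiencies from molar to per-molecule units
#'
#' `convert_catalytic_3d()` converts a 3D catalytic efficiency quoted in
#' \eqn{\mu M^{-1} s^{-1}} to nm\eqn{^3} s\eqn{^{-1}} (1 uM^-1 = 1e30 /
#' avogadro nm^3).  `convert_catalytic_2d()` converts an idealized 2D
#' efficiency quoted in \eqn{\mu M^{-1} s^{-1} m^{-1}} to
#' nm\eqn{^2} s\eqn{^{-1}} (the extra 1/m contributes a factor 1e-9 per nm).
#'
#' @param k Catalytic efficiency in uM^-1 s^-1 (3D) or uM^-1 s^-1 m^-1 (2D).
#' @param avogadro Avogadro constant, mol^-1; see [reach_avogadro()].
#' @return Rate in nm^3 s^-1 (3D) or nm^2 s^-1 (2D).
#' @export
#' @examples
#' convert_catalytic_3d(0.1)          # ~1.66e5 nm^3/s
#' convert_catalytic_2d((4 / 3) * 1e5) # ~221.37 nm^2/s
convert_catalytic_3d <- function(k, avogadro = reach_avogadro()) {
  if (any(k < 0)) stop("k must be >= 0")
  if (avogadro <= 0) stop("avogadro must be > 0")
  k * 1e30 / avogadro
}

#' @rdname convert_catalytic_3d
#' @export
convert_catalytic_2d <- function(k, avogadro = reach_avogadro()) {
  convert_catalytic_3d(k, avogadro) / 1e9
}

#' Gaussian reach kernel for a tethered reaction
#'
#' Bundles the molecular reach, the catalytic efficiency (already converted to
#' per-molecule units, see [convert_catalytic_3d()]) and the kernel
#' dimensionality.  The pairwise reaction propensity at anchor separation `r`
#' is `catalytic_efficiency * sigma(r; reach)`, in 1/s for either
#' dimensionality.
#'
#' @param reach Molecular reach L in nm (> 0).
#' @param catalytic_efficiency kcat in nm^3/s (3D kernel) or nm^2/s (2D).
#' @param dimension Kernel dimensionality, 3 (volume-proximal, physiological)
#'   or 2 (idealized in-plane).
#' @return Object of class `reach_kernel`.
#' @export
#' @examples
#' k <- reach_kernel(8.5, convert_catalytic_3d(0.1))
#' kernel_propensity(k, 0) # ~89/s at contact
reach_kernel <- function(reach, catalytic_efficiency, dimension = 3) {
  if (reach <= 0) stop("reach must be > 0")
  if (catalytic_efficiency < 0) stop("catalytic_efficiency must be >= 0")
  if (!dimension %in% c(2, 3)) stop("dimension must be 2 or 3")
  structure(list(
    reach = reach,
    catalytic_efficiency = catalytic_efficiency,
    dimension = as.integer(dimension)
  ), class = "reach_kernel")
}

#' @export
print.reach_kernel <- function(x, ...) {
  cat(sprintf("Gaussian %dD reach kernel: L = %g nm, kcat = %g nm^%d/s, kcat*sigma(0) = %.4g /s\n",
              x$dimension, x$reach, x$catalytic_efficiency, x$dimension,
              kernel_propensity(x, 0)))
  invisible(x)
}

#' Pairwise reaction propensity of a kernel at separation r
#'
#' @param kernel A [reach_kernel] or [calibrate_doi] object.
#' @param r Anchor separation(s) in nm.
#' @return Propensity in 1/s.
#' @export
kernel_propensity <- function(kernel, r) {
  if (inherits(kernel, "doi_calibration")) {
    return(ifelse(r <= kernel$epsilon, kernel$lam, 0))
  }
  sig <- if (kernel$dimension == 3L) sigma3d(r, kernel$reach) else sigma2d(r, kernel$reach)
  kernel$catalytic_efficiency * sig
}

#' Dimensionless Doi calibration ratios
#'
#' Ratio epsilon/L of the moment-matched indicator interaction radius to the
#' molecular reach: `doi_alpha()` = 16/(3 sqrt(6 pi)) ~ 1.2284 for the 3D
#' kernel, `doi_mu()` = sqrt(3 pi / 8) ~ 1.0854 for the 2D kernel.  Both
#' follow from matching the zeroth and first radial moments of the Gaussian
#' kernel with an indicator interaction (see [calibrate_doi()]).
#'
#' @return Dimensionless ratio.
#' @export
doi_alpha <- function() 16 / (3 * sqrt(6 * pi))

#' @rdname doi_alpha
#' @export
doi_mu <- function() sqrt(3 * pi / 8)

#' Moment-matched Doi (indicator) calibration of a Gaussian kernel
#'
#' Replaces the Gaussian interaction `kcat * sigma(r; L)` by an indicator
#' interaction `lam * 1\[0, epsilon\](r)` with the same total measure and the
#' same first radial moment.  For a 3D kernel the matched moments carry the
#' spherical weights r^2 and r^3 and give `epsilon = alpha * L` with
#' alpha = 16/(3 sqrt(6 pi)) and `lam = kcat / ((4/3) pi epsilon^3)`; for a
#' 2D kernel the planar weights r and r^2 give `epsilon = mu * L` with
#' mu = sqrt(3 pi / 8) and `lam = kcat / (pi epsilon^2)`.
#'
#' @param kernel A [reach_kernel].
#' @return Object of class `doi_calibration` with fields `epsilon` (nm),
#'   `lam` (1/s), `ratio` (epsilon/L), `dimension` and the source kernel.
#' @export
#' @examples
#' calibrate_doi(reach_kernel(8.5, convert_catalytic_3d(0.1)))
calibrate_doi <- function(kernel) {
  stopifnot(inherits(kernel, "reach_kernel"))
  if (kernel$catalytic_efficiency <= 0) stop("catalytic_efficiency must be > 0")
  if (kernel$dimension == 3L) {
    ratio <- doi_alpha()
    eps <- ratio * kernel$reach
    lam <- kernel$catalytic_efficiency / ((4 / 3) * pi * eps^3)
  } else {
    ratio <- doi_mu()
    eps <- ratio * kernel$reach
    lam <- kernel$catalytic_efficiency / (pi * eps^2)
  }
  structure(list(
    epsilon = eps, lam = lam, ratio = ratio,
    dimension = kernel$dimension, kernel = kernel
  ), class = "doi_calibration")
}

#' @export
print.doi_calibration <- function(x, ...) {
  cat(sprintf("Doi calibration (%dD kernel): epsilon = %.4g nm, lambda = %.4g /s (epsilon/L = %.6f)\n",
              x$dimension, x$epsilon, x$lam, x$ratio))
  invisible(x)
}
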