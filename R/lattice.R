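## Lattice domains, species, reaction rules and world construction.
##
## Canonical internal units: lengths in nm, times in s, diffusivities in
## nm^2/s.  User-facing constructors accept the field's conventional units
## (diffusivity in um^2/s, concentrations in molecules/nm^dim) and convert
## at the boundary.

#' Square or cubic lattice domain
#'
#' The simulation domain: a square (2D) or cube (3D) of side `side` nm,
#' discretized into `voxels_per_axis`^dimension voxels of spacing
#' `h = side/voxels_per_axis`, with periodic or reflecting boundaries.
#'
#' @param dimension 2 or 3.
#' @param side Side length in nm (default 300).
#' @param voxels_per_axis Voxels per axis (default 128 in 2D, 64 in 3D;
#'   powers of two keep refinement studies simple).
#' @param boundary "periodic" or "reflecting".
#' @return Object of class `lattice_domain` with the above fields plus
#'   `spacing` (nm) and `n_voxels`.
#' @export
#' @examples
#' lattice_domain(2, 300, 128)
lattice_domain <- function(dimension = 2, side = 300,
                           voxels_per_axis = if (dimension == 2) 128L else 64L,
                           boundary = c("periodic", "reflecting")) {
  boundary <- match.arg(boundary)
  if (!dimension %in% c(2, 3)) stop("dimension must be 2 or 3")
  if (side <= 0) stop("side must be > 0")
  voxels_per_axis <- as.integer(voxels_per_axis)
  if (voxels_per_axis < 1) stop("voxels_per_axis must be >= 1")
  structure(list(
    dimension = as.integer(dimension), side = side,
    voxels_per_axis = voxels_per_axis,
    spacing = side / voxels_per_axis,
    n_voxels = as.double(voxels_per_axis)^dimension,
    boundary = boundary
  ), class = "lattice_domain")
}

#' @export
print.lattice_domain <- function(x, ...) {
  cat(sprintf("%dD %s lattice: side %g nm, %d^%d voxels (h = %.4g nm)\n",
              x$dimension, x$boundary, x$side, x$voxels_per_axis, x$dimension,
              x$spacing))
  invisible(x)
}

#' Diffusing molecular species
#'
#' @param name Species identifier.
#' @param diffusivity Diffusion coefficient in um^2/s (table convention;
#'   converted to nm^2/s internally).
#' @param concentration Initial concentration in molecules/nm^2 (2D) or
#'   molecules/nm^3 (3D); see [per_um2()] for the per-um^2 convention of the
#'   push-pull model tables.
#' @return Object of class `species_def`.
#' @export
#' @examples
#' species_def("CD28", diffusivity = 0.1, concentration = 1e-4)
species_def <- function(name, diffusivity = 0, concentration = 0) {
  if (diffusivity < 0) stop("diffusivity must be >= 0")
  if (concentration < 0) stop("concentration must be >= 0")
  structure(list(name = as.character(name),
                 diffusivity = diffusivity,
                 diffusivity_nm2 = diffusivity * 1e6,
                 concentration = concentration),
            class = "species_def")
}

#' Convert a per-um^2 concentration to the canonical per-nm^2
#'
#' @param x Concentration in molecules/um^2.
#' @return Concentration in molecules/nm^2.
#' @export
#' @examples
#' per_um2(100) # 1e-4 nm^-2
per_um2 <- function(x) x * 1e-6

#' First-order reaction rule
#'
#' @param reactant,product Species names.
#' @param rate Rate in 1/s.
#' @return Object of class `unimolecular_rule`.
#' @export
#' @examples
#' unimolecular_rule("CD28", "CD28p", 1.0) # phosphorylation at 1/s
unimolecular_rule <- function(reactant, product, rate) {
  if (rate < 0) stop("rate must be >= 0")
  structure(list(reactant = reactant, product = product, rate = rate),
            class = "unimolecular_rule")
}

#' Separation-dependent pairwise tethered reaction rule
#'
#' A reaction `A + B -> product_of_a + product_of_b` firing at rate
#' `kernel_propensity(kernel, r)` for anchor separation `r` (minimal-image
#' distance between voxel centres on periodic domains).  Gaussian-kernel
#' propensities are truncated at `rcut = rcut_mult * L`, beyond which the
#' kernel is below ~1e-13 of its contact value; indicator kernels truncate
#' at their own radius.
#'
#' @param reactant_a,reactant_b Species names.
#' @param product_of_a,product_of_b Species the reactants convert to (an
#'   enzyme is typically unchanged: pass its own name).
#' @param kernel A [reach_kernel] or [calibrate_doi] object.
#' @param rcut_mult Gaussian truncation radius in units of the reach
#'   (default 4.5).
#' @return Object of class `pairwise_rule`.
#' @export
#' @examples
#' k <- reach_kernel(8.5, convert_catalytic_3d(0.1))
#' pairwise_rule("CD28p", "PD1", "CD28", "PD1", k)
pairwise_rule <- function(reactant_a, reactant_b, product_of_a, product_of_b,
                          kernel, rcut_mult = 4.5) {
  stopifnot(inherits(kernel, "reach_kernel") || inherits(kernel, "doi_calibration"))
  rcut <- if (inherits(kernel, "reach_kernel")) rcut_mult * kernel$reach
          else kernel$epsilon
  structure(list(reactant_a = reactant_a, reactant_b = reactant_b,
                 product_of_a = product_of_a, product_of_b = product_of_b,
                 kernel = kernel, rcut = rcut),
            class = "pairwise_rule")
}

#' Pairwise propensity of a rule at separation r
#'
#' @param rule A [pairwise_rule].
#' @param r Separation(s) in nm.
#' @return Propensity in 1/s (zero beyond the truncation radius).
#' @export
pair_propensity <- function(rule, r) {
  ifelse(r <= rule$rcut, kernel_propensity(rule$kernel, r), 0)
}

#' Reaction network: species plus rules
#'
#' @param species List of [species_def] objects.
#' @param unimolecular List of [unimolecular_rule] objects.
#' @param pairwise List of [pairwise_rule] objects.
#' @return Object of class `reaction_network`.
#' @export
reaction_network <- function(species, unimolecular = list(), pairwise = list()) {
  if (inherits(species, "species_def")) species <- list(species)
  nm <- vapply(species, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate species names")
  if (inherits(unimolecular, "unimolecular_rule")) unimolecular <- list(unimolecular)
  if (inherits(pairwise, "pairwise_rule")) pairwise <- list(pairwise)
  refs <- c(unlist(lapply(unimolecular, function(u) c(u$reactant, u$product))),
            unlist(lapply(pairwise, function(p) c(p$reactant_a, p$reactant_b,
                                                  p$product_of_a, p$product_of_b))))
  bad <- setdiff(refs, nm)
  if (length(bad)) stop("rules reference unknown species: ", paste(bad, collapse = ", "))
  structure(list(species = species, species_names = nm,
                 unimolecular = unimolecular, pairwise = pairwise),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("Reaction network: %d species, %d unimolecular, %d pairwise rules\n",
              length(x$species), length(x$unimolecular), length(x$pairwise)))
  invisible(x)
}

#' Hop propensity of a species on a lattice
#'
#' The continuous-time random-walk hop rate per lattice direction,
#' `D / h^2`; each molecule attempts `2 * dimension` directions.
#'
#' @param species A [species_def].
#' @param domain A [lattice_domain].
#' @return Hop rate per direction, 1/s.
#' @export
hop_propensity <- function(species, domain) {
  species$diffusivity_nm2 / domain$spacing^2
}

#' Minimal-image distance between two voxel centres
#'
#' @param domain A [lattice_domain].
#' @param voxel_i,voxel_j Integer coordinate vectors (1-based, each entry in
#'   `1:voxels_per_axis`).
#' @return Euclidean centre-to-centre distance in nm (minimal image on
#'   periodic domains).
#' @export
#' @examples
#' d <- lattice_domain(2, 300, 128)
#' pair_separation(d, c(1, 1), c(128, 1)) # wraps to one spacing
pair_separation <- function(domain, voxel_i, voxel_j) {
  n <- domain$voxels_per_axis
  if (length(voxel_i) != domain$dimension || length(voxel_j) != domain$dimension)
    stop("voxel coordinates must have length equal to the domain dimension")
  if (any(voxel_i < 1 | voxel_i > n) || any(voxel_j < 1 | voxel_j > n))
    stop("voxel index out of range")
  dx <- voxel_i - voxel_j
  if (domain$boundary == "periodic") {
    dx <- dx - n * round(dx / n)
  }
  sqrt(sum((dx * domain$spacing)^2))
}

#' Initialize a simulation world
#'
#' Molecule counts are `round(concentration * domain measure)` per species
#' (with a warning when rounding moves a count by more than 5%); positions
#' are sampled uniformly over voxels.  Pass `counts` to pin species counts
#' directly (overriding concentrations), and `positions` to pin coordinates.
#'
#' @param domain A [lattice_domain].
#' @param network A [reaction_network].
#' @param seed Optional integer; when given, `set.seed(seed)` is called
#'   first.  Leave NULL to draw from the current RNG stream (used by
#'   [run_ensemble()], which seeds per trajectory).
#' @param counts Optional named integer vector of molecule counts.
#' @param positions Optional list mapping species name to an integer matrix
#'   of 1-based voxel coordinates (rows = molecules).
#' @return Object of class `lattice_world`.
#' @export
#' @examples
#' dom <- lattice_domain(2, 300, 128)
#' net <- reaction_network(list(species_def("CD28", 0.1, 1e-4)))
#' build_world(dom, net, seed = 1) # 9 molecules on 300x300 nm^2
build_world <- function(domain, network, seed = NULL, counts = NULL,
                        positions = NULL) {
  stopifnot(inherits(domain, "lattice_domain"), inherits(network, "reaction_network"))
  if (!is.null(seed)) set.seed(seed)
  measure <- domain$side^domain$dimension
  nm <- network$species_names
  n_per <- integer(length(nm))
  for (i in seq_along(nm)) {
    if (!is.null(counts) && nm[i] %in% names(counts)) {
      n_per[i] <- as.integer(counts[[nm[i]]])
    } else {
      target <- network$species[[i]]$concentration * measure
      n_per[i] <- as.integer(round(target))
      if (target > 0 && abs(n_per[i] - target) / target > 0.05) {
        warning(warningCondition(
          sprintf("rounding changes %s count by %.1f%% (%.3g -> %d)",
                  nm[i], 100 * abs(n_per[i] - target) / target,
                  target, n_per[i]),
          class = "reachsim_count_rounding"))
      }
    }
  }
  n_tot <- sum(n_per)
  species <- rep(seq_along(nm), times = n_per)
  pos <- matrix(0L, n_tot, domain$dimension)
  row <- 1L
  for (i in seq_along(nm)) {
    if (n_per[i] == 0) next
    idx <- row:(row + n_per[i] - 1L)
    if (!is.null(positions) && nm[i] %in% names(positions)) {
      pm <- positions[[nm[i]]]
      if (nrow(pm) != n_per[i]) stop("positions for ", nm[i], " have wrong row count")
      pos[idx, ] <- as.integer(pm) - 1L   # to 0-based
    } else {
      for (k in seq_len(domain$dimension)) {
        pos[idx, k] <- sample.int(domain$voxels_per_axis, n_per[i],
                                  replace = TRUE) - 1L
      }
    }
    row <- row + n_per[i]
  }
  structure(list(domain = domain, network = network,
                 species = species, pos = pos, time = 0),
            class = "lattice_world")
}

#' @export
print.lattice_world <- function(x, ...) {
  tab <- table(factor(x$network$species_names[x$species],
                      levels = x$network$species_names))
  cat("Lattice world at t =", x$time, "s:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

## internal: propensity lookup table for one pairwise rule, indexed by the
## integer squared lattice distance m (r = h * sqrt(m)).
##
## The table is voxel-normalized (leading-order voxel averaging): it is
## rescaled so that the discrete sum of propensities over all minimal-image
## voxel offsets times h^d equals the continuum integral of the kernel over
## the same cell.  This is the zeroth-moment condition of the CRDME's
## voxel-averaged kernel: it leaves well-resolved kernels essentially
## untouched (factor -> 1 as h/L -> 0) and fixes the total reaction rate
## when the kernel is narrower than a voxel, so the simulated dynamics
## converge to the volume-reactivity model at any resolution.
make_pair_table <- function(rule, domain, normalize = TRUE) {
  key <- paste(class(rule$kernel)[1], rule$kernel$dimension,
               rule$kernel$reach, rule$kernel$catalytic_efficiency,
               rule$kernel$epsilon, rule$kernel$lam, rule$rcut,
               domain$dimension, domain$voxels_per_axis, domain$side,
               domain$boundary, normalize, sep = "|")
  cached <- .table_cache[[key]]
  if (!is.null(cached)) return(cached)

  nside <- domain$voxels_per_axis
  h <- domain$spacing
  d <- domain$dimension
  half <- if (domain$boundary == "periodic") nside %/% 2 else nside - 1L
  m_max_needed <- d * half^2
  ## truncate the table at the rule's cutoff to save memory
  m_cut <- min(m_max_needed, ceiling((rule$rcut / h)^2))
  r <- h * sqrt(0:m_cut)
  tab <- pair_propensity(rule, r)
  if (!normalize || all(tab == 0)) {
    .table_cache[[key]] <- tab
    return(tab)
  }

  ## minimal-image per-axis offsets of the fundamental cell
  ax <- (-(nside %/% 2 - 1L)):(nside %/% 2)
  ax <- pmin(abs(ax), nside - abs(ax))  # folded |offset|
  ## discrete sum of table values over all cell offsets, via per-m counts
  m_off <- if (d == 2) outer(ax^2, ax^2, "+")
           else outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  m_off <- m_off[m_off <= m_cut]
  discrete <- sum(tab[m_off + 1L]) * h^d
  ## continuum integral over the same cell: radial quadrature when the
  ## truncated kernel fits inside the minimal-image cell, otherwise a fine
  ## Cartesian subgrid (only wide, smooth kernels land there)
  if (rule$rcut <= (nside %/% 2) * h) {
    wgt <- if (d == 2) function(r) 2 * pi * r else function(r) 4 * pi * r^2
    cont <- stats::integrate(function(rr) pair_propensity(rule, rr) * wgt(rr),
                             0, rule$rcut, rel.tol = 1e-10,
                             subdivisions = 500L)$value
  } else {
    f <- h / 8
    axf <- seq(-nside * h / 2 + f / 2, nside * h / 2 - f / 2, by = f)
    if (d == 2) {
      rf <- sqrt(outer(axf^2, axf^2, "+"))
      cont <- sum(pair_propensity(rule, rf)) * f^d
    } else {
      r2 <- outer(axf^2, axf^2, "+")
      cont <- 0
      for (z in axf) cont <- cont + sum(pair_propensity(rule, sqrt(r2 + z^2)))
      cont <- cont * f^d
    }
  }
  out <- if (discrete > 0 && cont > 0) tab * (cont / discrete) else tab
  .table_cache[[key]] <- out
  out
}

## cache of normalized propensity tables, keyed by kernel + domain geometry
.table_cache <- new.env(parent = emptyenv())
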