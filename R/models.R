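## Receptor signaling models: PD-1 dephosphorylating CD28, and the
## kinase-phosphatase push-pull motif; steady-state detection and potency.

#' PD-1 / CD28 dephosphorylation model
#'
#' CD28 is phosphorylated by a first-order reaction at rate `lambda`
#' (standing in for membrane-anchored LCK) and dephosphorylated by PD-1
#' (PD-1/SHP-2 complexes; recruitment is not modeled) through the tethered
#' kernel `kcat * sigma(r; L)`.  Defaults follow the published parameter
#' table: `[CD28] = 1e-4 /nm^2`, `lambda = 1 /s`, `kcat = 0.1 /uM/s`,
#' periodic 300 nm square.
#'
#' @param pd1 PD-1 concentration, molecules/nm^2 (2D) or nm^3 (3D domain).
#' @param D Receptor diffusivity, um^2/s (applies to CD28, CD28p and PD-1).
#' @param L Molecular reach of the dephosphorylation reaction, nm.
#' @param lambda Phosphorylation rate, 1/s.
#' @param kcat Catalytic efficiency in uM^-1 s^-1 (3D kernel).
#' @param kcat_2d Catalytic efficiency in uM^-1 s^-1 m^-1 for the idealized
#'   2D kernel (required when `kernel_dim = 2`).
#' @param cd28 CD28 concentration, molecules/nm^dimension.
#' @param kernel_dim 3 (physiological volume-proximal kernel) or 2
#'   (idealized in-plane kernel).
#' @param dimension Diffusion dimension: 2 (membrane) or 3 (cube of
#'   cytosol).
#' @param side Domain side, nm.
#' @param voxels_per_axis Mesh resolution per axis.
#' @return Object of class `signaling_model`.
#' @export
#' @examples
#' m <- pd1_model(pd1 = 5e-4, D = 0.1, L = 8.5)
pd1_model <- function(pd1, D = 0.1, L = 8.5, lambda = 1.0, kcat = 0.1,
                      kcat_2d = NULL, cd28 = 1e-4, kernel_dim = 3,
                      dimension = 2, side = 300,
                      voxels_per_axis = if (dimension == 2) 128L else 64L) {
  args <- as.list(environment())
  if (kernel_dim == 2) {
    if (is.null(kcat_2d)) stop("kcat_2d (uM^-1 s^-1 m^-1) is required for the 2D kernel")
    kc <- convert_catalytic_2d(kcat_2d)
  } else {
    kc <- convert_catalytic_3d(kcat)
  }
  dom <- lattice_domain(dimension, side, voxels_per_axis, "periodic")
  kern <- reach_kernel(L, kc, dimension = kernel_dim)
  net <- reaction_network(
    list(species_def("CD28", D, cd28),
         species_def("CD28p", D, 0),
         species_def("PD1", D, pd1)),
    unimolecular = list(unimolecular_rule("CD28", "CD28p", lambda)),
    pairwise = list(pairwise_rule("CD28p", "PD1", "CD28", "PD1", kern)))
  structure(list(
    type = "pd1", constructor = "pd1_model", args = args,
    domain = dom, network = net, kernel = kern,
    unmodified = "CD28", modified = "CD28p", enzyme = "PD1",
    enzyme_arg = "pd1", gain_rate = lambda
  ), class = "signaling_model")
}

#' Kinase-phosphatase push-pull model
#'
#' Reversible modification of a substrate S by a kinase E and phosphatase F:
#' `S + E -> S* + E` through `kcat_e * sigma(r; L_e)` and `S* + F -> S + F`
#' through `kcat_f * sigma(r; L_f)`.  Defaults follow the published table:
#' `[S] = 100 /um^2`, `[F] = 112 /um^2`, `D_F = 6.25e-4 um^2/s`,
#' `kcat_e = 0.04 /uM/s`, `kcat_f = 0.01 /uM/s`, `L_f = 15 nm`, periodic
#' 300 nm square.  With the idealized 2D kernel the converted area-rates
#' default to the published values `kcat_e_2d = (4/3)e5` and
#' `kcat_f_2d = (1/3)e5 uM^-1 s^-1 m^-1`.
#'
#' @param E Kinase concentration, molecules/um^2 (2D; per um^3 in 3D).
#' @param D_S,D_E,D_F Diffusivities of substrate, kinase, phosphatase in
#'   um^2/s.
#' @param L_e,L_f Molecular reach of the kinase and phosphatase reactions,
#'   nm.
#' @param kcat_e,kcat_f 3D catalytic efficiencies, uM^-1 s^-1.
#' @param kcat_e_2d,kcat_f_2d 2D catalytic efficiencies, uM^-1 s^-1 m^-1
#'   (used when `kernel_dim = 2`).
#' @param S,F Substrate and phosphatase concentrations, molecules/um^2.
#' @param kernel_dim,dimension,side,voxels_per_axis As in [pd1_model()].
#' @return Object of class `signaling_model`.
#' @export
#' @examples
#' m <- pushpull_model(E = 500, D_S = 0.1, D_E = 0.1, L_e = 10)
pushpull_model <- function(E, D_S = 0.1, D_E = 0.1, L_e = 10,
                           kernel_dim = 3, D_F = 6.25e-4,
                           kcat_e = 0.04, kcat_f = 0.01,
                           kcat_e_2d = (4 / 3) * 1e5, kcat_f_2d = (1 / 3) * 1e5,
                           L_f = 15, S = 100, F = 112,
                           dimension = 2, side = 300,
                           voxels_per_axis = if (dimension == 2) 128L else 64L) {
  args <- as.list(environment())
  if (kernel_dim == 2) {
    kc_e <- convert_catalytic_2d(kcat_e_2d)
    kc_f <- convert_catalytic_2d(kcat_f_2d)
  } else {
    kc_e <- convert_catalytic_3d(kcat_e)
    kc_f <- convert_catalytic_3d(kcat_f)
  }
  ## concentrations are quoted per um^2 (or per um^3 for a 3D domain)
  unit <- if (dimension == 2) 1e-6 else 1e-9
  dom <- lattice_domain(dimension, side, voxels_per_axis, "periodic")
  kern_e <- reach_kernel(L_e, kc_e, dimension = kernel_dim)
  kern_f <- reach_kernel(L_f, kc_f, dimension = kernel_dim)
  net <- reaction_network(
    list(species_def("S", D_S, S * unit),
         species_def("Sp", D_S, 0),
         species_def("E", D_E, E * unit),
         species_def("F", D_F, F * unit)),
    pairwise = list(pairwise_rule("S", "E", "Sp", "E", kern_e),
                    pairwise_rule("Sp", "F", "S", "F", kern_f)))
  structure(list(
    type = "pushpull", constructor = "pushpull_model", args = args,
    domain = dom, network = net, kernel = kern_e, kernel_f = kern_f,
    unmodified = "S", modified = "Sp", enzyme = "E",
    enzyme_arg = "E", gain_rate = NULL
  ), class = "signaling_model")
}

#' @export
print.signaling_model <- function(x, ...) {
  cat(sprintf("%s model (%dD diffusion, %dD kernel) on %g nm %s domain\n",
              toupper(x$type), x$domain$dimension, x$kernel$dimension,
              x$domain$side, x$domain$boundary))
  print(x$network)
  invisible(x)
}

#' Rebuild a signaling model with modified parameters
#'
#' @param model A [pd1_model()] or [pushpull_model()] object.
#' @param ... Constructor arguments to override (e.g. `L_e = 70`,
#'   `D = 1.25e-6`, or the enzyme concentration).
#' @return A new `signaling_model`.
#' @export
update_model <- function(model, ...) {
  do.call(model$constructor, utils::modifyList(model$args, list(...)))
}

## internal: spatial-mean per-pair reaction rate (1/s) of a pairwise rule on
## the model's domain: k_RL / measure, where k_RL is the kernel integral
## over the diffusion space (planar integral of sigma3d = sqrt(3/(2 pi))/L
## times kcat; unit integral for matching dimensions)
mean_pair_rate <- function(kernel, domain) {
  meas <- domain$side^domain$dimension
  k_RL <- if (kernel$dimension == 3L && domain$dimension == 2L) {
    kernel$catalytic_efficiency * sqrt(3 / (2 * pi)) / kernel$reach
  } else {
    kernel$catalytic_efficiency  # kernel integrates to 1 over its own space
  }
  k_RL / meas
}

## internal: mean-field linearization of a model: per-molecule gain/loss
## rates, relaxation rate kappa and stationary modified fraction p0
mean_field <- function(model) {
  dom <- model$domain
  meas <- dom$side^dom$dimension
  count_of <- function(name) {
    sp <- model$network$species[[match(name, model$network$species_names)]]
    round(sp$concentration * meas)
  }
  if (model$type == "pd1") {
    gain <- model$args$lambda
    loss <- mean_pair_rate(model$kernel, dom) * count_of("PD1")
  } else {
    gain <- mean_pair_rate(model$kernel, dom) * count_of("E")
    loss <- mean_pair_rate(model$kernel_f, dom) * count_of("F")
  }
  kappa <- gain + loss
  list(gain = gain, loss = loss, kappa = kappa,
       p0 = if (kappa > 0) gain / kappa else 0)
}

#' Steady-state modified fraction of a signaling model
#'
#' Runs an ensemble of trajectories and returns the time-averaged modified
#' fraction `[modified] / ([modified] + [unmodified])` with its standard
#' error across trajectories.
#'
#' Steady-state policy: the mean-field linearization of the model gives a
#' relaxation rate `kappa` and stationary fraction `p0`.  When diffusion
#' mixes the domain faster than reactions relax (`side^2/(4 (D_sub + D_enz))
#' < 1/kappa`) the system is effectively well-mixed: trajectories are
#' warm-started with modification states drawn Bernoulli(`p0`) and run for
#' `(burn + avg)/kappa` relaxation times, averaging over the final `avg`
#' portion.  Otherwise (slow diffusion) trajectories cold-start from the
#' unmodified state and run to at least `t_floor`, averaging over the final
#' half.  Convergence is declared when the two halves of the averaging
#' window agree within `2 * pooled SE`; the result carries a `converged`
#' flag.
#'
#' @param model A `signaling_model`.
#' @param n_trajectories Ensemble size.
#' @param base_seed Integer seed; trajectory k uses `base_seed + k - 1`.
#' @param burn,avg Burn-in and averaging windows in units of `1/kappa`
#'   (defaults 1.5 each).
#' @param t_floor Minimum horizon (s) for slow-diffusion (cold-start) runs,
#'   default 200.
#' @param warm_start TRUE/FALSE, or "auto" (the mixing-time rule above).
#' @return Object of class `steady_state`: `fraction`, `se`, `converged`,
#'   per-trajectory fractions, and the resolved policy.
#' @export
steady_state_fraction <- function(model, n_trajectories = 200, base_seed = 1,
                                  burn = 1.5, avg = 1.5, t_floor = 200,
                                  warm_start = "auto") {
  stopifnot(inherits(model, "signaling_model"))
  mf <- mean_field(model)
  dom <- model$domain
  nm <- model$network$species_names
  i_mod <- match(model$modified, nm)
  i_unmod <- match(model$unmodified, nm)
  D_sub <- model$network$species[[i_unmod]]$diffusivity_nm2
  D_enz <- model$network$species[[match(model$enzyme, nm)]]$diffusivity_nm2
  t_mix <- dom$side^2 / (4 * max(D_sub + D_enz, 1e-12))
  if (identical(warm_start, "auto")) {
    ## warm start is justified whenever diffusion can actually mix the
    ## domain on a short absolute timescale; very slow diffusion leaves a
    ## quenched spatial arrangement that the mean-field p0 cannot describe
    warm_start <- mf$kappa > 0 && t_mix < 5
  }
  if (warm_start && mf$kappa > 0) {
    tau_sys <- max(1 / mf$kappa, t_mix)   # slower of reaction relaxation/mixing
    t_end <- (burn + avg) * tau_sys
    avg_start <- burn * tau_sys
    init <- function(w) {
      is_un <- w$species == i_unmod
      flip <- is_un & (stats::runif(length(w$species)) < mf$p0)
      w$species[flip] <- i_mod
      w
    }
  } else {
    t_end <- max(if (mf$kappa > 0) (burn + avg) / mf$kappa else 0, t_floor)
    avg_start <- t_end / 2
    init <- NULL
  }
  ens <- run_ensemble(dom, model$network, t_end = t_end,
                      n_trajectories = n_trajectories, base_seed = base_seed,
                      avg_start = avg_start, init = init)
  frac <- ens$avg[, model$modified] /
    (ens$avg[, model$modified] + ens$avg[, model$unmodified])
  f1 <- ens$avg_first_half[, model$modified] /
    (ens$avg_first_half[, model$modified] + ens$avg_first_half[, model$unmodified])
  f2 <- ens$avg_second_half[, model$modified] /
    (ens$avg_second_half[, model$modified] + ens$avg_second_half[, model$unmodified])
  ok <- is.finite(frac)
  n_ok <- sum(ok)
  se <- if (n_ok > 1) stats::sd(frac[ok]) / sqrt(n_ok) else NA_real_
  pooled <- sqrt(stats::var(f1[ok]) / n_ok + stats::var(f2[ok]) / n_ok)
  converged <- is.finite(pooled) &&
    abs(mean(f2[ok]) - mean(f1[ok])) < 2 * max(pooled, 1e-12)
  structure(list(
    fraction = mean(frac[ok]), se = se, converged = converged,
    per_trajectory = frac,
    policy = list(warm_start = warm_start, t_end = t_end,
                  avg_start = avg_start, kappa = mf$kappa, p0 = mf$p0,
                  t_mix = t_mix),
    n_trajectories = n_trajectories, base_seed = base_seed
  ), class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("Steady-state modified fraction: %.4f +- %.4f (%d trajectories, %s, %sconverged)\n",
              x$fraction, x$se, x$n_trajectories,
              if (x$policy$warm_start) "warm start" else "cold start",
              if (x$converged) "" else "NOT "))
  invisible(x)
}

#' Half-maximal concentration from a dose-response curve
#'
#' Primary estimator: monotone (isotonic) smoothing of the mean curve in the
#' detected direction, then log-linear interpolation between the two grid
#' points bracketing the half-maximal level.  A four-parameter Hill fit is
#' attempted as a cross-check only.
#'
#' @param concentration Concentration grid (> 0).
#' @param fraction Mean response at each concentration.
#' @param level Response level defining the half-maximal point; default the
#'   midpoint of the isotonic fit's range.
#' @return List with `ic50` (NA when the curve does not cross `level`, with
#'   `bracket` giving the bound), `direction` ("decreasing" = IC50,
#'   "increasing" = EC50), the isotonic fit, `level`, and `hill` (fitted
#'   midpoint, or NA if the fit fails).
#' @export
#' @examples
#' conc <- 10^seq(-1, 3, length.out = 9)
#' extract_ic50(conc, 1 / (1 + conc / 10))$ic50 # ~10
extract_ic50 <- function(concentration, fraction, level = NULL) {
  if (length(concentration) < 4) stop("need at least 4 grid points")
  if (any(concentration <= 0)) stop("concentrations must be > 0 (log interpolation)")
  o <- order(concentration)
  conc <- concentration[o]; y <- fraction[o]
  decreasing <- stats::cor(log(conc), y, method = "spearman") < 0
  iso <- if (decreasing) -stats::isoreg(log(conc), -y)$yf
         else stats::isoreg(log(conc), y)$yf
  if (is.null(level)) level <- (min(iso) + max(iso)) / 2
  dy <- iso - level
  cross <- which(dy[-length(dy)] * dy[-1] <= 0 & dy[-length(dy)] != dy[-1])
  if (!length(cross) && !any(dy == 0)) {
    side <- if (all(dy > 0) == decreasing) "above" else "below"
    return(list(ic50 = NA_real_,
                bracket = if (xor(all(dy > 0), decreasing)) c(NA, conc[1])
                          else c(conc[length(conc)], NA),
                direction = if (decreasing) "decreasing" else "increasing",
                iso = iso, level = level, note = paste("curve stays", side),
                hill = NA_real_))
  }
  if (any(dy == 0) && !length(cross)) {
    ic50 <- conc[which(dy == 0)[1]]
  } else {
    i <- cross[1]
    f <- dy[i] / (dy[i] - dy[i + 1])
    ic50 <- exp(log(conc[i]) + f * (log(conc[i + 1]) - log(conc[i])))
  }
  hill <- tryCatch(suppressWarnings({
    top <- max(iso); bot <- min(iso)
    fit <- stats::nls(y ~ bot_ + (top_ - bot_) / (1 + (conc / c0)^(s * h)),
                      start = list(bot_ = bot, top_ = top, c0 = ic50, h = 1),
                      data = list(y = y, conc = conc,
                                  s = if (decreasing) 1 else -1),
                      control = stats::nls.control(warnOnly = TRUE))
    unname(stats::coef(fit)["c0"])
  }), error = function(e) NA_real_)
  list(ic50 = ic50, bracket = NULL,
       direction = if (decreasing) "decreasing" else "increasing",
       iso = iso, level = level, hill = hill)
}

#' Dose-response sweep over enzyme concentration
#'
#' Computes the steady-state modified fraction over a concentration grid of
#' the model's inhibitory or activating enzyme and extracts the
#' half-maximal concentration (IC50 for an inhibitor such as PD-1, EC50 for
#' the push-pull kinase).
#'
#' @param model A `signaling_model`; the sweep rebuilds it at each grid
#'   concentration (units as the model constructor's enzyme argument).
#' @param sweep Concentration grid (>= 4 points).
#' @param n_trajectories,base_seed,... Passed to
#'   [steady_state_fraction()]; the same `base_seed` is reused across grid
#'   points (common random numbers).
#' @return Object of class `dose_response`: `concentration`, `fraction`,
#'   `se`, `converged`, `ic50` (from [extract_ic50()]), `monotone`
#'   (trend check within 2 SE), and metadata.
#' @export
dose_response <- function(model, sweep, n_trajectories = 200, base_seed = 1, ...) {
  if (length(sweep) < 4) stop("sweep needs >= 4 grid points")
  res <- lapply(sweep, function(cc) {
    m <- do.call(update_model,
                 stats::setNames(list(model, cc), c("model", model$enzyme_arg)))
    steady_state_fraction(m, n_trajectories = n_trajectories,
                          base_seed = base_seed, ...)
  })
  fr <- vapply(res, `[[`, numeric(1), "fraction")
  se <- vapply(res, `[[`, numeric(1), "se")
  ic <- extract_ic50(sweep, fr)
  dir_sign <- if (ic$direction == "decreasing") -1 else 1
  viol <- diff(fr) * dir_sign < -2 * sqrt(se[-1]^2 + se[-length(se)]^2)
  structure(list(
    concentration = sweep, fraction = fr, se = se,
    converged = vapply(res, `[[`, logical(1), "converged"),
    ic50 = ic, monotone = !any(viol),
    n_trajectories = n_trajectories, base_seed = base_seed,
    enzyme = model$enzyme, type = model$type
  ), class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  lab <- if (x$ic50$direction == "decreasing") "IC50" else "EC50"
  cat(sprintf("Dose-response over [%s] (%d points, %d trajectories each)\n",
              x$enzyme, length(x$concentration), x$n_trajectories))
  cat(sprintf("  %s = %.4g (%s trend %sviolated)\n", lab, x$ic50$ic50,
              x$ic50$direction, if (x$monotone) "not " else ""))
  invisible(x)
}

#' @export
plot.dose_response <- function(x, ...) {
  plot(x$concentration, x$fraction, log = "x", ylim = c(0, 1),
       xlab = sprintf("[%s]", x$enzyme), ylab = "modified fraction",
       pch = 19, ...)
  graphics::arrows(x$concentration, x$fraction - x$se,
                   x$concentration, x$fraction + x$se,
                   angle = 90, code = 3, length = 0.03)
  if (is.finite(x$ic50$ic50)) graphics::abline(v = x$ic50$ic50, lty = 2)
  invisible(x)
}

#' Potency over a reach x diffusivity grid
#'
#' Runs [dose_response()] at each combination of molecular reach and
#' diffusivity and collects the half-maximal concentrations; the sign
#' structure of this surface carries the potency switch (with the 3D kernel
#' on a membrane, potency improves with reach at slow diffusion and worsens
#' at fast diffusion; with the 2D kernel it never worsens).
#'
#' @param model A `signaling_model`.
#' @param reach_grid Reaches (nm) substituted into the model's reach
#'   argument (`L` for PD-1, `L_e` for push-pull).
#' @param diffusivity_grid Diffusivities (um^2/s) substituted for the
#'   mobile species (`D` for PD-1; `D_S` and `D_E` for push-pull).
#' @param sweep,n_trajectories,base_seed,... Passed to [dose_response()].
#' @return Object of class `potency_surface`: matrix `ic50`
#'   (reach x diffusivity), the grids, and the list of `dose_response`
#'   fits.
#' @export
potency_surface <- function(model, reach_grid, diffusivity_grid, sweep,
                            n_trajectories = 200, base_seed = 1, ...) {
  reach_arg <- if (model$type == "pd1") "L" else "L_e"
  ic <- matrix(NA_real_, length(reach_grid), length(diffusivity_grid),
               dimnames = list(paste0("L", reach_grid), paste0("D", diffusivity_grid)))
  fits <- vector("list", length(ic))
  dim(fits) <- dim(ic)
  for (i in seq_along(reach_grid)) {
    for (j in seq_along(diffusivity_grid)) {
      upd <- stats::setNames(list(reach_grid[i]), reach_arg)
      upd[[if (model$type == "pd1") "D" else "D_S"]] <- diffusivity_grid[j]
      if (model$type == "pushpull") upd$D_E <- diffusivity_grid[j]
      m <- do.call(update_model, c(list(model), upd))
      dr <- dose_response(m, sweep, n_trajectories = n_trajectories,
                          base_seed = base_seed, ...)
      ic[i, j] <- dr$ic50$ic50
      fits[[i, j]] <- dr
    }
  }
  structure(list(ic50 = ic, reach_grid = reach_grid,
                 diffusivity_grid = diffusivity_grid, fits = fits),
            class = "potency_surface")
}

#' @export
print.potency_surface <- function(x, ...) {
  cat("Half-maximal concentration surface (rows: reach, cols: diffusivity):\n")
  print(signif(x$ic50, 4))
  invisible(x)
}
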