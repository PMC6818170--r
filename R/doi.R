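## Two-particle Doi (volume-reactivity) mean-reaction-time theory.
##
## One molecule is fixed at the origin of a disc (d = 2) or sphere (d = 3) of
## radius R; the other diffuses with diffusivity D and the pair reacts at rate
## lam whenever their separation is below epsilon.  The mean reaction time
## w(r) from initial separation r solves
##
##   D r^(1-d) d/dr( r^(d-1) dw/dr ) - lam 1_[0,eps](r) w = -1,   w'(R) = 0,
##
## with w(0) finite.  The well-mixed mean reaction time <T> is the
## d-dimensional radial average of w.

#' Radius of the disc/sphere with the same measure as a square/cube
#'
#' @param side Side length of the square (2D) or cube (3D), nm.
#' @param dimension 2 or 3.
#' @return Radius R in nm: `side/sqrt(pi)` (2D) or `side*(3/(4 pi))^(1/3)` (3D).
#' @export
#' @examples
#' equal_measure_radius(300, 2) # ~169.26 nm
equal_measure_radius <- function(side, dimension = 2) {
  if (any(side <= 0)) stop("side must be > 0")
  if (dimension == 2) side / sqrt(pi)
  else if (dimension == 3) side * (3 / (4 * pi))^(1 / 3)
  else stop("dimension must be 2 or 3")
}

#' Two-particle Doi mean-reaction-time problem
#'
#' @param dimension Diffusion dimension d (2 = membrane patch, 3 = cytosolic
#'   volume).
#' @param R Domain radius, nm.
#' @param D Diffusivity of the mobile molecule, nm^2/s.
#' @param epsilon Doi interaction radius, nm.
#' @param lam Doi contact reaction rate, 1/s.
#' @return Object of class `doi_problem`; `rho` (epsilon/R) and `Rhat`
#'   (R sqrt(lam/D)) are available via [doi_rho()] and [doi_Rhat()].
#' @export
doi_problem <- function(dimension, R, D, epsilon, lam) {
  if (!dimension %in% c(2, 3)) stop("dimension must be 2 or 3")
  if (R <= 0 || D <= 0 || epsilon <= 0 || lam <= 0) {
    stop("R, D, epsilon and lam must all be > 0")
  }
  structure(list(dimension = as.integer(dimension), R = R, D = D,
                 epsilon = epsilon, lam = lam),
            class = "doi_problem")
}

#' @rdname doi_problem
#' @param problem A `doi_problem`.
#' @export
doi_rho <- function(problem) problem$epsilon / problem$R

#' @rdname doi_problem
#' @export
doi_Rhat <- function(problem) problem$R * sqrt(problem$lam / problem$D)

#' @export
print.doi_problem <- function(x, ...) {
  cat(sprintf("Doi problem (d = %d): R = %.4g nm, D = %.4g nm^2/s, epsilon = %.4g nm, lambda = %.4g /s (rho = %.4g)\n",
              x$dimension, x$R, x$D, x$epsilon, x$lam, doi_rho(x)))
  invisible(x)
}

#' Exact well-mixed mean reaction time of the Doi problem
#'
#' Closed-form solution of the radial boundary-value problem.  On the disc
#' (d = 2) the interior solution involves modified Bessel functions and, for
#' `rho = epsilon/R <= 1`,
#' \deqn{\langle T\rangle = \frac1\lambda
#'   + \frac1\lambda\Big[1+\frac{\hat R^2-\hat R^2\rho^2}{2\hat R\rho}
#'     \frac{I_0(\hat R\rho)}{I_1(\hat R\rho)}\Big](1-\rho^2)
#'   - \frac{R^2}{8D}\big[\rho^4-4\rho^2+3+4\ln\rho\big]}
#' with \eqn{\hat R = R\sqrt{\lambda/D}}; on the sphere (d = 3) the interior
#' solution involves \eqn{\sinh(\beta r)/r} and the analogous closed form is
#' assembled from hyperbolic functions.  When the reaction zone covers the
#' whole domain (`rho > 1`) the mean reaction time is `1/lam` from every
#' starting point.  Bessel and hyperbolic ratios are evaluated in
#' exponentially scaled form, so extreme `Rhat * rho` does not overflow.
#'
#' @param problem A [doi_problem].
#' @return The well-mixed mean reaction time in s.
#' @export
#' @examples
#' cal <- calibrate_doi(reach_kernel(8.5, convert_catalytic_3d(0.1)))
#' p <- doi_problem(2, equal_measure_radius(300, 2), 1e5, cal$epsilon, cal$lam)
#' mrt_exact(p)
mrt_exact <- function(problem) {
  stopifnot(inherits(problem, "doi_problem"))
  rho <- doi_rho(problem)
  if (rho >= 1) return(1 / problem$lam)
  if (problem$dimension == 2L) mrt_exact_disc(problem) else mrt_exact_sphere(problem)
}

## d = 2 branch of mrt_exact (disc)
mrt_exact_disc <- function(problem) {
  lam <- problem$lam; D <- problem$D; R <- problem$R
  rho <- doi_rho(problem); Rhat <- doi_Rhat(problem)
  x <- Rhat * rho  # = beta * epsilon
  ## I0/I1 ratio; scaling factors cancel
  ratio <- besselI(x, 0, expon.scaled = TRUE) / besselI(x, 1, expon.scaled = TRUE)
  term2 <- (1 / lam) * (1 + (Rhat^2 - Rhat^2 * rho^2) / (2 * Rhat * rho) * ratio) * (1 - rho^2)
  term3 <- -(R^2 / (8 * D)) * (rho^4 - 4 * rho^2 + 3 + 4 * log(rho))
  1 / lam + term2 + term3
}

## d = 3 branch of mrt_exact (sphere).  Interior solution
## w1 = 1/lam + A sinh(beta r)/r; exterior w2 = -r^2/6D - R^3/(3 D r) + B.
## Flux matching at epsilon gives A; only the stable combination
## A sinh(beta*eps)/eps = (R^3 - eps^3) / (3 D eps^2 (beta/tanh(beta*eps) - 1/eps))
## is needed, which is overflow-free for large beta*eps.
mrt_exact_sphere <- function(problem) {
  lam <- problem$lam; D <- problem$D; R <- problem$R; eps <- problem$epsilon
  beta <- sqrt(lam / D)
  x <- beta * eps
  ## A*sinh(beta*eps)/eps without forming sinh/cosh separately
  w1eps_A <- (R^3 - eps^3) / (3 * D * eps^2 * (beta / tanh(x) - 1 / eps))
  B <- 1 / lam + w1eps_A + eps^2 / (6 * D) + R^3 / (3 * D * eps)
  ## <T> = 1/lam + (3/R^3) * int_eps^R w2 r^2 dr   (interior integral collapses
  ## to R^3/(3 lam), see the flux identity A*(eps cosh/beta - sinh/beta^2) =
  ## (R^3-eps^3)/(3 lam))
  int2 <- -(R^5 - eps^5) / (30 * D) - (R^3 / (3 * D)) * (R^2 - eps^2) / 2 +
    B * (R^3 - eps^3) / 3
  1 / lam + (3 / R^3) * int2
}

#' Finite-volume solution of the Doi mean-reaction-time problem
#'
#' Independent numerical oracle for [mrt_exact()]: a conservative
#' finite-volume discretization of the radial boundary-value problem on a
#' graded mesh.  The mesh is refined geometrically around the reaction-zone
#' edge `r = epsilon`, where the solution has a boundary layer of width
#' `sqrt(D/lam)`; the indicator coefficient is volume-averaged exactly over
#' each control volume, and the no-flux condition at R and regularity at 0
#' are imposed through vanishing face fluxes.
#'
#' @param problem A [doi_problem].
#' @param n_base Number of base mesh cells across `[0, R]` (default 4000).
#' @param layer_div Cells per interior decay length `sqrt(D/lam)` at the
#'   reaction-zone edge (default 24).
#' @param richardson Solve at two resolutions and Richardson-extrapolate
#'   `T_mean` (the scheme is second order, verified by the ratio of the two
#'   refinement errors).  Default TRUE.
#' @return Object of class `mrt_solution` with the node radii `r`, the mean
#'   reaction time profile `w` (finest solve), the well-mixed mean `T_mean`
#'   and the problem.
#' @export
solve_mrt_numeric <- function(problem, n_base = 4000, layer_div = 24,
                              richardson = TRUE) {
  stopifnot(inherits(problem, "doi_problem"))
  s1 <- mrt_fv_solve(problem, 1, n_base, layer_div)
  if (!richardson) {
    return(structure(c(s1, list(method = "numeric", problem = problem)),
                     class = "mrt_solution"))
  }
  s2 <- mrt_fv_solve(problem, 2, n_base, layer_div)
  structure(list(r = s2$r, w = s2$w,
                 T_mean = (4 * s2$T_mean - s1$T_mean) / 3,
                 method = "numeric", problem = problem),
            class = "mrt_solution")
}

## One finite-volume solve at refinement factor f: graded mesh with spacing
## hmin at the interface growing geometrically to h0 = R/(n_base f), exact
## radial-resistance face conductances, exact control-volume average of the
## indicator, Thomas solve.
mrt_fv_solve <- function(problem, f, n_base, layer_div) {
  R <- problem$R; eps <- min(problem$epsilon, R)
  lam <- problem$lam; D <- problem$D; d <- problem$dimension
  delta <- sqrt(D / lam)                    # interior decay length
  h0 <- R / (n_base * f)
  grow <- 1 + 0.12 / f
  hmin <- max(min(h0, delta / (layer_div * f), eps / (40 * f)), R * 1e-10)

  grade <- function(from, to, h_start, h_cap) {
    if (to <= from) return(numeric(0))
    out <- numeric(0); x <- from; h <- h_start
    while (x < to) {
      x <- min(x + h, to)
      out <- c(out, x)
      h <- min(h * grow, h_cap)
    }
    out
  }
  cap_in <- min(h0, eps / (40 * f))         # keeps >= 40f cells inside the zone
  left <- eps - grade(0, eps, hmin, cap_in)
  right <- eps + grade(0, R - eps, hmin, h0)
  r <- sort(unique(c(0, pmax(left, 0), eps, pmin(right, R), R)))
  r <- r[c(TRUE, diff(r) > hmin * 1e-3)]
  if (r[length(r)] != R) r <- c(r, R)
  n <- length(r)

  ## faces r_{i+1/2}; the outermost faces at 0 and R carry zero flux
  face <- c(0, (r[-1] + r[-n]) / 2, R)
  Vi <- (face[-1]^d - face[-(n + 1)]^d) / d     # CV measure (angular factor dropped)
  lam_bar <- lam * (pmin(eps, face[-1])^d - pmin(eps, face[-(n + 1)])^d) /
    (face[-1]^d - face[-(n + 1)]^d)

  ## face conductance: exact radial resistance integral between node centres
  ## (log form for d = 2, harmonic for d = 3); midpoint-face fallback next to
  ## r = 0 where the integral diverges (flux vanishes there by regularity)
  drs <- diff(r)
  cond <- if (d == 2) D / log(r[2:n] / pmax(r[1:(n - 1)], 1e-300))
          else D * r[2:n] * r[1:(n - 1)] / drs
  cond[1] <- D * face[2]^(d - 1) / drs[1]
  diag_main <- -lam_bar * Vi
  diag_main[1:(n - 1)] <- diag_main[1:(n - 1)] - cond
  diag_main[2:n] <- diag_main[2:n] - cond
  rhs <- -Vi

  ## Thomas algorithm
  cp <- numeric(n - 1); dp <- numeric(n)
  cp[1] <- cond[1] / diag_main[1]
  dp[1] <- rhs[1] / diag_main[1]
  for (i in 2:n) {
    m <- diag_main[i] - cond[i - 1] * cp[i - 1]
    if (i < n) cp[i] <- cond[i] / m
    dp[i] <- (rhs[i] - cond[i - 1] * dp[i - 1]) / m
  }
  w <- numeric(n)
  w[n] <- dp[n]
  for (i in (n - 1):1) w[i] <- dp[i] - cp[i] * w[i + 1]

  list(r = r, w = w, T_mean = sum(Vi * w) / sum(Vi))
}

#' @export
print.mrt_solution <- function(x, ...) {
  cat(sprintf("MRT solution (%s, d = %d): <T> = %.6g s over %d nodes\n",
              x$method, x$problem$dimension, x$T_mean,
              length(x$r)))
  invisible(x)
}

#' @export
plot.mrt_solution <- function(x, ...) {
  plot(x$r, x$w, type = "l", xlab = "initial separation r (nm)",
       ylab = "mean reaction time w(r) (s)", ...)
  abline(v = x$problem$epsilon, lty = 2, col = "grey50")
  invisible(x)
}

## internal: map model label to (diffusion dimension, kernel dimension)
model_dims <- function(model) {
  model <- match.arg(model, c("2.5D", "2D", "3D"))
  switch(model,
    "2.5D" = list(model = model, d_diff = 2L, d_kernel = 3L),
    "2D"   = list(model = model, d_diff = 2L, d_kernel = 2L),
    "3D"   = list(model = model, d_diff = 3L, d_kernel = 3L))
}

#' Asymptotic well-mixed mean reaction time for small reach
#'
#' Small-`rho` expansions of the well-mixed mean reaction time for the three
#' model geometries (`rho = epsilon/R`):
#' \itemize{
#' \item 2.5D (diffusion in the membrane, 3D kernel, `kcat` in nm^3/s):
#'   \eqn{(4/3)\pi R^2 \alpha L / k_{cat} - (R^2/4D) 2\ln(\alpha L/R) - R^2/4D}
#' \item 2D (2D kernel, `kcat` in nm^2/s):
#'   \eqn{\pi R^2 / k_{cat} - (R^2/4D) 2\ln(\mu L/R) - R^2/4D}
#' \item 3D (diffusion in the cytosol, 3D kernel):
#'   \eqn{(4/3)\pi R^3 / k_{cat} + 2R^3/(5 D \alpha L) - 3R^2/5D}
#' }
#' The expansions lose accuracy as `rho` grows; the result carries a `valid`
#' flag that is FALSE for `rho > 0.2`.
#'
#' @param model "2.5D", "2D" or "3D".
#' @param kcat Catalytic efficiency in nm^3/s (3D kernel) or nm^2/s (2D).
#' @param L Molecular reach, nm.
#' @param D Diffusivity, nm^2/s.
#' @param R Domain radius, nm.
#' @return List with `T` (s), `rho` and `valid`.
#' @export
mrt_asymptotic <- function(model, kcat, L, D, R) {
  md <- model_dims(model)
  if (md$d_kernel == 3L) {
    eps <- doi_alpha() * L
  } else {
    eps <- doi_mu() * L
  }
  rho <- eps / R
  T <- switch(md$model,
    "2.5D" = (4 / 3) * pi * R^2 * eps / kcat -
      (R^2 / (4 * D)) * 2 * log(eps / R) - R^2 / (4 * D),
    "2D" = pi * R^2 / kcat -
      (R^2 / (4 * D)) * 2 * log(eps / R) - R^2 / (4 * D),
    "3D" = (4 / 3) * pi * R^3 / kcat + 2 * R^3 / (5 * D * eps) -
      3 * R^2 / (5 * D))
  list(T = T, rho = rho, valid = rho <= 0.2)
}

#' Reaction-limited / diffusion-limited decomposition of the mean reaction time
#'
#' Splits the leading asymptotic behaviour of the well-mixed mean reaction
#' time into a reaction-limited part `T_RL` (diffusion infinitely fast) and
#' the leading diffusion-limited part `T_DL` (instant reaction on contact):
#' \itemize{
#' \item 2.5D: `k_RL = kcat * sqrt(3/(2 pi)) / L` (the planar integral of the
#'   3D kernel), `T_RL = pi R^2 / k_RL` (proportional to L),
#'   `T_DL = (R^2/2D) ln(R/(alpha L))`, reconstruction coefficient 32/(9 pi);
#' \item 2D: `k_RL = kcat` (unit planar integral), `T_RL = pi R^2 / kcat`
#'   (independent of L), `T_DL = (R^2/2D) ln(R/(mu L))`, coefficient 1;
#' \item 3D: `k_RL = kcat`, `T_RL = (4/3) pi R^3 / kcat` (independent of L),
#'   `T_DL = R^3/(3 D alpha L)`, coefficient 6/5.
#' }
#' `T_reconstructed = coef * T_RL + coef_DL * T_DL + constant` equals the
#' corresponding [mrt_asymptotic()] value.
#'
#' @inheritParams mrt_asymptotic
#' @return List with `T_RL`, `T_DL`, `k_RL`, the reconstruction coefficients
#'   and `T_reconstructed` (s).
#' @export
mrt_decompose <- function(model, kcat, L, D, R) {
  md <- model_dims(model)
  if (md$model == "2.5D") {
    k_RL <- kcat * sqrt(3 / (2 * pi)) / L
    T_RL <- pi * R^2 / k_RL
    T_DL <- (R^2 / (2 * D)) * log(R / (doi_alpha() * L))
    coef_RL <- 32 / (9 * pi); coef_DL <- 1
    const <- -R^2 / (4 * D)
  } else if (md$model == "2D") {
    k_RL <- kcat
    T_RL <- pi * R^2 / kcat
    T_DL <- (R^2 / (2 * D)) * log(R / (doi_mu() * L))
    coef_RL <- 1; coef_DL <- 1
    const <- -R^2 / (4 * D)
  } else {
    k_RL <- kcat
    T_RL <- (4 / 3) * pi * R^3 / kcat
    T_DL <- R^3 / (3 * D * doi_alpha() * L)
    coef_RL <- 1; coef_DL <- 6 / 5
    const <- -3 * R^2 / (5 * D)
  }
  list(T_RL = T_RL, T_DL = T_DL, k_RL = k_RL,
       coef_RL = coef_RL, coef_DL = coef_DL, constant = const,
       T_reconstructed = coef_RL * T_RL + coef_DL * T_DL + const)
}

#' Well-mixed mean reaction time of a tethered pair
#'
#' High-level entry point tying kernel calibration, geometry and the Doi
#' solution together for the three model geometries: "2.5D" (diffusion in the
#' membrane, reaction through the 3D kernel -- the physiological case), "2D"
#' (diffusion and reaction in the plane) and "3D" (diffusion and reaction in
#' the cytosolic volume).  The Gaussian kernel `kcat * sigma(r; L)` is
#' replaced by its moment-matched indicator ([calibrate_doi()]); the square
#' (cube) domain of side `side` is replaced by the disc (sphere) of equal
#' measure.  When the matched interaction radius exceeds the domain radius
#' (`rho > 1`) the reaction zone covers the domain and `<T> = 1/lam`,
#' i.e. `(4/3) pi (alpha L)^3 / kcat` in the 2.5D case.
#'
#' @param model "2.5D", "2D" or "3D".
#' @param kcat Catalytic efficiency in nm^3/s for 3D kernels ("2.5D", "3D")
#'   or nm^2/s for the 2D kernel ("2D"); see [convert_catalytic_3d()].
#' @param L Molecular reach, nm.
#' @param D Diffusivity in um^2/s (the usual convention for membrane
#'   diffusivities; converted to nm^2/s internally).
#' @param side Side of the square/cube domain, nm (default 300).
#' @param method "exact" (closed form), "numeric" (finite-volume oracle) or
#'   "asymptotic".
#' @return List with `T` (s), `T_RL`, `T_DL`, `epsilon`, `lambda`, `rho`,
#'   `R`, `method` and `valid` (FALSE when an asymptotic result is used
#'   outside its domain).
#' @export
#' @examples
#' mrt_wellmixed("2.5D", convert_catalytic_3d(0.1), L = 8.5, D = 0.1)
mrt_wellmixed <- function(model, kcat, L, D, side = 300,
                          method = c("exact", "numeric", "asymptotic")) {
  md <- model_dims(model)
  method <- match.arg(method)
  D_nm <- D * 1e6
  R <- equal_measure_radius(side, md$d_diff)
  cal <- calibrate_doi(reach_kernel(L, kcat, dimension = md$d_kernel))
  rho <- cal$epsilon / R
  valid <- TRUE
  if (rho >= 1) {
    T <- 1 / cal$lam
  } else if (method == "exact") {
    T <- mrt_exact(doi_problem(md$d_diff, R, D_nm, cal$epsilon, cal$lam))
  } else if (method == "numeric") {
    T <- solve_mrt_numeric(doi_problem(md$d_diff, R, D_nm, cal$epsilon, cal$lam))$T_mean
  } else {
    a <- mrt_asymptotic(md$model, kcat, L, D_nm, R)
    T <- a$T; valid <- a$valid
  }
  dec <- mrt_decompose(md$model, kcat, L, D_nm, R)
  list(T = T, T_RL = dec$T_RL, T_DL = dec$T_DL,
       epsilon = cal$epsilon, lambda = cal$lam, rho = rho, R = R,
       model = md$model, method = method, valid = valid)
}
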