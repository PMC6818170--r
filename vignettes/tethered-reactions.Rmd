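---
title: "Modeling tethered membrane signaling reactions with reachsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling tethered membrane signaling reactions with reachsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachsim)
```

## The biological problem

Many surface receptors signal through *tethered* reactions: a cytosolic
enzyme binds the unstructured cytoplasmic tail of one receptor and then
modifies substrates it can physically reach.  The canonical example built
into this package is the inhibitory checkpoint receptor PD-1, whose tail
recruits the phosphatase SHP-2; the tethered SHP-2 dephosphorylates the
costimulatory receptor CD28.  Both receptors diffuse in the two-dimensional
plasma membrane, but their tails and the bound enzyme explore the
three-dimensional cytoplasmic volume next to it.

The geometry of that exploration is summarized by a single biophysical
parameter, the **molecular reach** $L$ of the reaction.  Treating each
unstructured segment as a worm-like chain (WLC) with persistence length
$l_p$ and contour length $l_c$, each component contributes a reach
$\sqrt{l_p l_c}$, and components combine in quadrature,
$L = \sqrt{L_1^2 + L_2^2 + \dots}$.  With $l_p = 0.4$ nm and a 0.4 nm
backbone step per residue, the CD28 segment (11 residues to the YMNM
tyrosine) gives $L_\mathrm{CD28} \approx 1.3$ nm, the PD-1 segment (56
residues to the ITSM tyrosine) $L_\mathrm{PD\text{-}1} \approx 3.0$ nm, and
with a 7.9 nm estimate for SHP-2 the reach of the full dephosphorylation
reaction is $\approx 8.5$ nm (`wlc_reach()`, `combined_reach()`).  The
SHP-2 value is accepted as a literal input (7.9 nm default; 17.1 nm if its
flexible linkers were fully extended) because the package does not model
enzyme structure.

## Interaction kernels

For two anchors separated by an in-membrane distance $r$, the equilibrated
WLC tails meet with probability density

$$\sigma_{3D}(r; L) = \left(\frac{3}{2\pi L^2}\right)^{3/2}
  e^{-3r^2/(2L^2)},$$

normalized over free 3D space (a free-space form is used even though the
membrane occludes a half-space: the two kernels differ only by a constant
factor, which is absorbed into the catalytic efficiency).  A tethered reaction with catalytic efficiency
$k_\mathrm{cat}$ then fires at rate $k_\mathrm{cat}\sigma_{3D}(r;L)$, with
units 1/s when $k_\mathrm{cat}$ is a volume rate (nm$^3$/s).  To ask what
the 3D excursions of the tails contribute, the package also provides the
idealized planar kernel

$$\sigma_{2D}(r; L) = \frac{3}{2\pi L^2} e^{-3r^2/(2L^2)},$$

which forces the reaction to happen within the membrane plane and pairs
with an area-rate $k_\mathrm{cat}$ (nm$^2$/s).  Catalytic efficiencies
quoted in $\mu M^{-1} s^{-1}$ (3D) or $\mu M^{-1} s^{-1} m^{-1}$ (2D) are
converted by `convert_catalytic_3d()` / `convert_catalytic_2d()` using the
rounded Avogadro constant $6.023\times10^{23}$; this historical rounding is
deliberate, because it reproduces published converted rates such as
221.3736 nm$^2$/s to five significant figures.

## The lattice simulator

`simulate_world()` samples a continuous-time jump process: molecules hop
between voxels of a square/cubic mesh at rate $D/h^2$ per direction
(periodic wrap, or rejected hops at reflecting walls — a self-loop that
leaves the law of the process unchanged), first-order rules fire with
exponential clocks, and pairwise tethered rules fire at the
separation-dependent rates above, evaluated at minimal-image voxel-centre
distances.  Sampling is the exact direct (Gillespie) method; pairwise
propensities are maintained incrementally and rebuilt after every reaction
event, so floating-point drift cannot accumulate.

Two discretization choices matter:

* **Truncation.** Gaussian propensities are cut off at $r > 4.5L$, where
  the kernel is below $10^{-13}$ of its contact value (`rcut_mult`).
* **Voxel normalization.** Propensity lookup tables are rescaled so that
  the discrete sum of rates over all voxel offsets times the voxel measure
  equals the continuum integral of the kernel (the zeroth moment of the
  voxel-averaged kernel).  For well-resolved kernels ($h \ll L$) the factor
  is indistinguishable from 1; when a kernel is narrower than a voxel it
  prevents the total reaction rate from being inflated by
  centre-evaluation, so steady states converge to the volume-reactivity
  (Doi) model at any mesh.  With reaches of ~1 nm the radial *shape* of
  the kernel is still unresolved below $h \approx 1$ nm; refinement
  studies with `voxels_per_axis` quantify the residual.

Default meshes are $128^2$ (2D) and $64^3$ (3D); tests and the bundled
switch experiment run at $64^2$, chosen so that the full experiment
completes on one desktop CPU while the refinement-stability test (32 vs
64 voxels per axis at a resolved reach) guards the approximation.

Reproducibility: trajectory $k$ of an ensemble is seeded with
`base_seed + k - 1`; the event loop uses a xoshiro256++ generator seeded
from R's stream, so everything is reproducible through `set.seed()` and
ensembles sharing a base seed are coupled by common random numbers (used
by the monotonicity and switch tests to cancel shared noise).

## Signaling models

`pd1_model()` implements CD28 phosphorylation as a first-order reaction
(rate $\lambda$, replacing explicit LCK kinetics) opposed by tethered
dephosphorylation, CD28$^*$ + PD-1 $\to$ CD28 + PD-1 at
$k^*_\mathrm{cat}\sigma_{3D}(r;L)$.  `[PD-1]` denotes PD-1·SHP-2
complexes; recruitment is not modeled.  `pushpull_model()` implements the
generic kinase/phosphatase pair S + E $\to$ S$^*$ + E and S$^*$ + F $\to$
S + F.  Defaults are the published parameter tables (CD28 at
$10^{-4}$/nm$^2$, $\lambda = 1$/s, $k^*_\mathrm{cat} = 0.1\,\mu$M$^{-1}$s$^{-1}$;
S at 100/$\mu$m$^2$, F at 112/$\mu$m$^2$, $D^F = 6.25\times10^{-4}\,\mu$m$^2$/s,
$k^e_\mathrm{cat} = 0.04$, $k^f_\mathrm{cat} = 0.01\,\mu$M$^{-1}$s$^{-1}$,
$L^f = 15$ nm, 300 nm periodic squares).

### Steady-state policy

The mean-field linearization of either model gives a relaxation rate
$\kappa$ (sum of per-molecule modification and demodification rates, with
the spatially averaged pair rate $k_{RL}/A$) and a stationary fraction
$p_0$.  The policy in `steady_state_fraction()`:

* **Warm start (mixing faster than ~5 s).**  Modification states are
  initialized Bernoulli($p_0$), the system is burned in for
  `burn` $\times \max(1/\kappa,\, t_\mathrm{mix})$ and averaged over the
  following `avg` multiples of the same timescale (defaults 1.5 each;
  the bundled switch experiment uses 0.75 to keep desk-scale runtimes).
  With the warm start the remaining transient is the small gap between
  $p_0$ and the true spatially correlated steady state, which the burn-in
  erases.
* **Cold start (quenched, slow diffusion).**  Trajectories start
  unmodified and run to at least `t_floor` (200 s), averaging over the
  final half.  In this regime molecule positions are effectively frozen;
  the reported fraction is the quasi-steady state of the quenched
  configuration, which is the quantity that carries the slow-diffusion
  phenotype.  Pairs coupled by extremely small rates equilibrate only on
  diffusive timescales and are deliberately left to the horizon chosen.

Convergence is declared when the two halves of the averaging window agree
within twice the pooled standard error; results carry a `converged` flag,
and doubling the burn-in is tested to leave the answer unchanged.

### Potency extraction

`dose_response()` sweeps the enzyme concentration and `extract_ic50()`
extracts the half-maximal point: isotonic (monotone) smoothing of the mean
curve in the detected direction, then log-linear interpolation between the
two grid points bracketing the level (half of the isotonic range by
default; pass `level = 0.5` when the curve's full range is known to be
[0, 1]).  Interpolation is assumption-light; a four-parameter Hill fit is
reported as a cross-check only.  On synthetic inhibitor curves
$f(c) = 1/(1 + c/c_0)$ with 1% additive noise on a 9-point log grid, the
recovered $c_0$ is unbiased within a few percent (mean absolute error
~3–4%; single replicates can err by ~10%).

## Two-particle Doi theory

To explain the simulations, one A molecule is fixed at the origin of a
disc (2.5D/2D) or sphere (3D) whose measure matches the simulation square
or cube (`equal_measure_radius()`), and the Gaussian interaction is
replaced by an indicator: rate $\lambda$ inside radius $\varepsilon$.
Matching the kernel's zeroth and first radial moments
(`calibrate_doi()`) gives

$$\varepsilon = \alpha L,\quad \alpha = \frac{16}{3\sqrt{6\pi}} \approx 1.2284,
\qquad \lambda = \frac{k_\mathrm{cat}}{\tfrac43\pi\varepsilon^3}$$

for the 3D kernel, and $\varepsilon = \mu L$ with
$\mu = \sqrt{3\pi/8} \approx 1.0854$, $\lambda = k_\mathrm{cat}/(\pi\varepsilon^2)$
for the 2D kernel.  The mean reaction time $w(r)$ from initial separation
$r$ solves a radial two-point boundary-value problem with a no-flux outer
wall, and the well-mixed mean $\langle T\rangle$ is its radial average.

`mrt_exact()` implements the closed forms — modified Bessel functions on
the disc, hyperbolic functions on the sphere, both evaluated through
exponentially scaled ratios so extreme $\hat R\rho$ cannot overflow — and
`solve_mrt_numeric()` provides an independent finite-volume oracle:
exact radial-resistance face conductances, exact control-volume averaging
of the indicator, a mesh graded geometrically into the reaction-zone
boundary layer of width $\sqrt{D/\lambda}$, and Richardson extrapolation
over a verified second-order refinement pair.  The two agree to better
than $10^{-6}$ relative error across the full diffusivity/reach grid used
in the tests, which is the package's strongest internal consistency check.

### Asymptotics and their domain of validity

For $\rho = \varepsilon/R \ll 1$ the well-mixed mean reaction time is
approximated by

$$\langle T\rangle \sim
\begin{cases}
\frac43\pi R^2 \frac{\alpha L}{k_\mathrm{cat}} - \frac{R^2}{4D}\,2\ln\frac{\alpha L}{R} - \frac{R^2}{4D} & \text{(2.5D)}\\[4pt]
\frac{\pi R^2}{k_\mathrm{cat}} - \frac{R^2}{4D}\,2\ln\frac{\mu L}{R} - \frac{R^2}{4D} & \text{(2D)}\\[4pt]
\frac43\pi \frac{R^3}{k_\mathrm{cat}} + \frac{2R^3}{5D\alpha L} - \frac{3R^2}{5D} & \text{(3D)}
\end{cases}$$

(`mrt_asymptotic()`), and `mrt_decompose()` splits each into a
reaction-limited time $T_{RL}$ (infinitely fast diffusion) and a leading
diffusion-limited time $T_{DL}$ (instant reaction on contact).  The key
structural fact is that $k_{RL}$, the effective well-mixed bimolecular
rate, equals the kernel's integral over the space the molecules diffuse
in: for the 2.5D case that is the *planar* integral of a *3D* kernel,
$k_\mathrm{cat}\sqrt{3/(2\pi)}/L$, which decays like $1/L$ — so
$T_{RL}^{2.5D} \propto L$, while in the 2D and 3D cases $T_{RL}$ is
independent of $L$.

A caution established numerically in this package: these expansions are
derived at fixed $\hat R = R\sqrt{\lambda/D}$, i.e. in the
reaction-influenced regime $x = \hat R\rho \lesssim 1$.  Under the
calibration $\lambda \propto L^{-3}$, slow diffusivities put the system
deep in the diffusion-limited regime ($x \gg 1$), where the true constant
terms differ (for the disc, $-\tfrac34 R^2/2D$ rather than
$-\tfrac12 R^2/2D$; for the sphere the $T_{DL}$ coefficient tends to 1
rather than 6/5).  Measured against the exact solutions, the expansions
are accurate to well under 2% for $D \gtrsim 10^{-2}\,\mu$m$^2$/s at
$\rho \le 0.05$, but deviate by up to ~6% (2.5D), ~4% (2D) and ~20% (3D)
at $D = 1.25\times10^{-6}\,\mu$m$^2$/s.  `mrt_asymptotic()` therefore
returns a validity flag, and the exact/numeric paths are the reference.

## The potency switch

The headline phenomenon ties everything together.  In the physiological
configuration (2.5D: diffusion in the membrane, reaction through the 3D
kernel), $\langle T\rangle(L{=}70) < \langle T\rangle(L{=}1)$ at
$D = 1.25\times10^{-6}\,\mu$m$^2$/s but
$\langle T\rangle(L{=}70) > \langle T\rangle(L{=}1)$ at
$D = 0.1\,\mu$m$^2$/s: longer reach helps slowly diffusing receptors and
hurts rapidly diffusing ones, because the reaction-limited time grows
with $L$ (the tails dilute their reactive sites over a volume $\sim L^3$
while only gaining an encounter area $\sim L^2$) whereas the
diffusion-limited time shrinks with $L$.  Forcing the reaction into the
plane ($\sigma_{2D}$) or letting molecules diffuse in 3D makes $T_{RL}$
independent of $L$ and the switch disappears.  The same inversion appears
in the stochastic push-pull model: at $[E] = 1111/\mu$m$^2$ the
steady-state phospho-fraction ordering between $L^e = 1$ and $70$ nm
inverts between slow and fast diffusion with the 3D kernel and does not
invert with the 2D kernel.  The bundled experiment uses 500 trajectories
per condition on a $64^2$ mesh with the short warm-started window
described above — deliberately desk-scale; it resolves orderings with
non-overlapping 1-SE bars but not the published curves themselves.

## What the models do and do not capture

The simulator emulates: 2D/3D diffusion of discrete molecules at
physiological densities, exact reaction timing, tethered kernels with
calibrated reach, and steady-state dose-response logic.  It does not
emulate: SHP-2 recruitment kinetics, explicit LCK, receptor clustering or
cytoskeletal corrals, crowding/excluded volume, multisite
phosphorylation/processivity, non-Gaussian kernels for
membrane-interacting tails, or high-density steric effects.  Passing tests
therefore demonstrate internal consistency of the model chain
(kernel → lattice process → steady state → potency; theory → simulation),
not quantitative agreement with any particular cell's biology.

## Numerical summary of scales used in checks

* Oracle grids: 6 diffusivities ($1.25\times10^{-6}$–$0.1\,\mu$m$^2$/s)
  $\times$ 6 reaches (1–70 nm), agreement $<10^{-6}$.
* Two-particle Monte Carlo: 2,000 trajectories per point at $128^2$;
  agreement within 3 SE of the disc value (disc-vs-square and residual
  lattice bias measured at about 2–3%, inside that band).
* Push-pull switch: 500 trajectories per condition at $64^2$.
* Exactness: $10^4$ waiting-time samples (KS), $>10^6$ hop events for the
  occupancy test, 200 replicates for mean-squared displacement.
```
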