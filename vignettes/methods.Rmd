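---
title: "Modelling signal-controlled spinal cord regeneration: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling signal-controlled spinal cord regeneration: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(ependysim)
```

## The model

After tail amputation, the axolotl spinal cord regrows because ependymal
cells — the neural stem cells lining the central canal — accelerate their
cell cycle. The accelerating cue is treated here as a generic signal that
is produced at the posterior wound front, diffuses through the tissue with
coefficient $D$, and is degraded at rate $k$. `ependysim` couples two
scales on a two-dimensional strip (anterior–posterior axis $x$ by
circumference $y$, periodic in $y$):

* **Cellular scale.** Cells are hard discs of common radius $R$. Each cell
  carries a non-Markovian cell-cycle clock: a total cycle length drawn
  from a lognormal distribution (slow program: mean 340 h, sd 32 h; fast
  program: 119 h, sd 10 h) and an age within the cycle. A cell divides
  when its age reaches its cycle length; one daughter keeps the mother's
  position, the other is placed at a uniform distance in $(0, 2R)$ within
  a half-angle $\pi/8$ of the posterior direction. Overlaps created by
  division are removed by relaxing a short-range repulsion potential
  $\Phi(r) = 2\kappa R^2 (r-1)^2$, $r = d/2R < 1$, to its steady state. A
  simplified *Poisson* variant replaces the clocks with memoryless
  division frequencies $\nu_S < \nu_F$.

* **Signalling scale.** The signal density obeys
  $\partial_t \rho_s = D \Delta \rho_s - k \rho_s$ with $\rho_s = \rho_0$
  on the moving posterior front and $\rho_s = 0$ at the fixed anterior
  wall. It is solved with a smoothed-particle (SPH) discretization:
  equal-mass particles estimate their local density through the 2D Poly6
  kernel of support radius $h$ and move along their regularized density
  gradient ("diffusion velocity"), $\dot Z_j = -D \nabla\rho_j / (\rho_j +
  \rho^*)$; degradation removes each particle with probability
  $1 - e^{-k\,\Delta t}$ per step; the Dirichlet source is enforced by
  holding the particle count in the front strip $[L - 2R,\, L]$ at
  $N_S = 2R\,W\,\rho_0 / m$.

* **Coupling.** A cell whose centre sees an SPH density above the
  threshold $\rho_s^{min}$ — and at least two signalling particles within
  the kernel radius — is *recruited*: its clock switches irreversibly to
  the fast program (G1 partially skipped, S mapped proportionally, G2/M
  remaining time preserved), and all progeny inherit the recruited state.
  Recruited cells divide faster, the tissue elongates, the front (and its
  signal source) moves posteriorly.

The *recruitment limit* $\xi(t)$ — the position of the most anteriorly
recruited cell, in coordinates centred on the amputation plane — is the
model's central observable, because its experimental counterpart (the
switchpoint between high- and low-proliferation zones) has been measured
during axolotl regeneration.

## The fast reaction–diffusion theory

When diffusion and degradation are much faster than cell cycling, the
signal relaxes instantaneously to the steady state
$$\rho_s(x) = \rho_0\,\frac{\sinh(x/\lambda)}{\sinh(L/\lambda)},
 \qquad \lambda = \sqrt{D/k},$$
and the threshold crossing sits at
$x^*(L) = \lambda\,\mathrm{asinh}\!\big(\tfrac{\rho_s^{min}}{\rho_0}
\sinh(L/\lambda)\big)$. Cells posterior of $x^*(L_0)$ are recruited at
once; with Poisson division frequencies the two zones then grow as
$L_s(t) = (\xi(0)+L_0)e^{\nu_S t}$ and $L_f(t) = -\xi(0)e^{\nu_F t}$ with
$\xi(0) = x^*(L_0) - L_0$, and the outgrowth is $L_s + L_f - L_0$. If the
initial condition satisfies
$$\nu_F L_F(0) > \nu_S L_S(0)\,
  \frac{\sqrt{(\rho_0/\rho_s^{min})^2 - 1}}{\cosh(L_0/\lambda)},$$
the threshold position stays inside the already-recruited zone for all
times, no further cell is recruited, and the closed forms are exact
(`proposition1_condition()`, `integrate_growth_ode()`).

**Which curve is "the" theoretical recruitment limit?** In the regime
where the condition above holds, recruitment stops after the initial
instant, so the most anteriorly recruited cell sits at the slow/fast zone
boundary and the theoretical recruitment limit is $L_s(t) - L_0$. Outside
that regime recruitment is ongoing and the limit tracks the threshold
crossing $x^*(L(t)) - L_0$. Both expressions coincide at $t = 0$.
`theory_recruitment_limit()` selects the applicable branch automatically
(argument `regime`). This distinction matters: the threshold-crossing
curve races posteriorly with the whole tissue, while the boundary curve —
the object an agent-based simulation (or an experiment tracking recruited
cells) actually measures in this regime — moves at the slow-zone pace.

## Parameters, units and defaults

Configuration accepts the units in which the biology is usually quoted
and converts internally to hours and micrometres.

| parameter | default | units | meaning |
|---|---|---|---|
| `D` | 1 | um^2/s | signal diffusion coefficient |
| `k` | 1 | 1/day | degradation rate (half-life $\ln 2 / k$) |
| `rhos_min` | 3 | signal units/um^2 | recruitment threshold |
| `rho0` | 40 | signal units/um^2 | source density at the front |
| `particle_mass` | 400 | signal units | mass of one SPH particle |
| `h` | `4 * R` | um | SPH kernel support radius |
| `rho_star` | `rho0/100` | signal units/um^2 | gradient regularization |
| `R` | 7 | um | cell radius |
| `L0` | 1000 | um | initial tissue length |
| `ymax - ymin` | 180 | um | circumference of the strip |
| `kappa` | 1 | arbitrary | repulsion intensity (only the fixed point matters) |
| slow cycle | 340 (32) | h | lognormal mean (sd), non-recruited |
| fast cycle | 119 (10) | h | lognormal mean (sd), recruited |
| phase fractions | 0.45/0.45/0.10 slow; 0.20/0.68/0.12 fast | — | G1/S/G2+M shares |
| `nu_slow`, `nu_fast` | $\ln 2/340$, $\ln 2/119$ | 1/h | Poisson division frequencies |
| `theta_star` | $\pi/8$ | rad | daughter placement half-angle |

The cycle-length moments are experimental measurements from regenerating
and uninjured axolotl spinal cords; the geometry (R, circumference, L0),
`kappa`, `rho0` and the phase fractions are documented defaults chosen to
be biologically plausible rather than fitted quantities — the tissue-level
observables this package targets constrain only the ratio
$\rho_s^{min}/\rho_0$ and the cycle moments, not these internals. The
Poisson frequencies default to the doubling rates of the two mean cycle
lengths, which makes the two division models agree in expectation.

**Particle mass.** The Dirichlet source count is
$N_S = 2R\,W\,\rho_0/m$. With unit-mass particles the density scale at
which recruitment thresholds of order 3–30 are meaningful would require
$10^5$–$10^6$ particles; the mass parameter decouples the density scale
from the particle count, with `m = 400` putting roughly 0.1 particle per
um^2 at the source. Convergence studies below use smaller masses (finer
clouds).

**Initial conditions.** Cells are thrown uniformly at 1.05 times the
close-packed disc count, relaxed to a non-overlapping configuration, and
trimmed at $L_0$: the tissue starts *at* its jammed packing fraction.
This matters: if the packing starts loose, early divisions are silently
absorbed as densification instead of elongation and the growth law falls
below $e^{\nu t}$. The realized initial front (mean front-cell $x$) is
taken as the amputation plane for all reported coordinates. Initial ages
follow the truncated density $\propto 2^{-2C/T}$ on $[0, T)$; the printed
normalization of that density integrates to 3/4, so the package uses the
renormalized version and samples it by its exact inverse CDF.

## Numerical choices

* **Time step.** $\Delta t = \min(C (2R)^2/D,\ 1/k)$ with $C = 1/2$,
  further capped so $k \Delta t \le 0.1$ (accurate Poisson removal), by an
  absolute 0.5 h (so division events stay resolved when diffusion is
  slow), and by a kernel-aware displacement cap $2Rh/(5D)$. The drift
  speed of the particle scheme is bounded by roughly $3.4\,D/h$ in the
  worst (strongly anisotropic) neighbourhood, so the last cap keeps every
  displacement below one cell diameter; at the default $h = 4R$ it
  coincides with the classical bound up to the safety factor. Rare
  cluster geometries can still exceed the nominal bound slightly, so the
  hard failure in `diffusion_step()` triggers at 1.5 times it.

* **Overlap relaxation.** Explicit-Euler descent on the repulsion
  potential with step $0.2/\kappa$ (safely inside the per-pair stability
  limit $0.5/\kappa$) and per-iteration displacements capped at $0.25R$.
  The descent stops when the largest overlap falls below `relax_tol`
  times the diameter (engine default 0.02). The model's non-overlap
  *invariant* is a tenth of a diameter; stopping the descent there,
  however, lets the packing compact a little after every division and the
  tissue absorbs growth instead of elongating — the tighter stopping
  tolerance keeps the packing fraction stationary. Two corner cases are
  handled deterministically when the descent stalls: a pressurized
  packing may balance small residual overlaps against neighbour forces
  (accepted, provided the tenth-of-a-diameter invariant holds), and pairs
  wedged at the anterior wall — including over-full wall rows, where more
  discs are pressed against the wall than the circumference can hold —
  are resolved by projecting cells apart to exact contact, posteriorly
  where the wall blocks the anterior component.

* **SPH resolution and bias.** The scheme's effective transport carries
  two finite-resolution biases with opposite signs: the noisy
  density/gradient ratio estimator *under*-transports (it shrinks with
  the kernel-neighbour count), and discreteness near the thin source
  strip *over*-drives the profile. At the engine's default resolution the
  steady-state amplitude sits 15–30% below the analytic profile; the
  validation configuration (`particle_mass = 50`, `h = 20` um, slow
  diffusion) brings the full profile within a few percent. The packaged
  steady-state validation (acceptance test) runs a fixed domain of
  L = 500 um at characteristic length 100 um on a 30 um-wide strip and
  compares the time-averaged binned particle density against
  $\rho_0 \sinh(x/\lambda)/\sinh(L/\lambda)$.

* **Stable special functions.** All $\sinh$ ratios and $\mathrm{asinh}$
  calls are evaluated through exponential-shifted logarithms, because the
  theory is routinely used at $L/\lambda$ up to about 100 where naive
  $\sinh$ overflows.

* **Randomness.** One seeded generator drives everything; every stochastic
  ingredient (initialization, cycle draws, degradation, refill, division,
  placement) consumes it in a fixed documented order, so a run is
  bit-reproducible given its seed.

## The synthetic data generators

No deposited experimental datasets accompany the biological studies this
model addresses, so the calibration module generates synthetic stand-ins
with the same shapes:

* `synth_switchpoint_curve()` emulates a recruitment-limit time series
  over days 0–8: daily samples of the theoretical $\xi(t)$ plus i.i.d.
  Gaussian noise, with the generating $\lambda$ recorded.
* `synth_fucci_profiles()` emulates per-animal spatial fractions of cells
  in G0/G1 versus S/G2 along the AP axis (the two channels of a
  fluorescent cell-cycle reporter): a seeded simulation provides the
  underlying profile and per-animal binomial sampling noise is added per
  spatial bin.

These emulate sampling noise and between-animal variability, but not
systematic experimental effects (segmentation errors, tissue curvature,
staging differences). Tests that pass against these generators therefore
validate the machinery — error metrics, sweeps, recovery — not the
biology of any particular dataset.

## Fitting

`curve_error()` implements the trapezoid-rule time integral of the
squared absolute difference between two curves; `fit_sweep()` evaluates
it between a reference recruitment-limit curve and seed-averaged model
curves over a `(D, k)` grid and accepts points below `eps_fit`. The
tolerance defaults to 0.5 with the error computed on millimetre-scaled
curves: recruitment limits span close to a millimetre over eight days, and
on that scale a tolerance of 0.5 admits roughly a quarter-millimetre
average deviation, which reproduces the "accepted band along constant
$\lambda$" structure. (On raw micrometre curves the same number would be
unsatisfiable — every squared error would be of order $10^3$–$10^5$.)
`relative_phase_error()` scores simulated phase profiles against
per-animal references: per animal and channel, the curve error is
normalized by the error of that animal's profile against zero, and the
minimum over channels and animals is reported.

## Desk-scale validation sizes

The packaged acceptance tests run minutes, not days, so they use reduced
problem sizes chosen once: a 60 um circumference (40 um for the
sensitivity ladder) instead of 180 um, an initial tissue of 400 um
instead of 1000 um, and particle masses of 50–400 depending on the
resolution each check needs. The fast-limit comparisons (Poisson variant
against the closed forms) run at $\lambda = 41.74$ um with
$\rho_s^{min}/\rho_0 = 0.5$ and five seeds per parameter set: the
recruitment-limit check uses two diffusion coefficients fast enough for
the instantaneous-profile assumption (0.5 and 1 um^2/s), while the
error-versus-speed trend uses a slower ladder (0.005–0.08 um^2/s) whose
signal transients of 0.2–3 days are comparable to cell cycling — that is
the regime in which the transient, not the particle-sampling noise floor,
dominates the deviation from the closed forms. The parameter-recovery
check drives the sweep with the closed-form forward model at the full
data scale (a simulation-driven sweep at that scale is outside a desk
budget; simulator–theory agreement is established by the fast-limit
comparisons).

## Known limitations

* The SPH amplitude bias at coarse resolution shifts the effective
  characteristic length by 10–20%; quantitative work should use the
  validated finer resolution or check convergence in `particle_mass`/`h`.
* Density fluctuations near the threshold produce occasional
  fluctuation-driven recruitment slightly anterior of the deterministic
  threshold position (an irreversible ratchet of order the fluctuation
  scale times $\lambda$); it shrinks with finer particle clouds.
* The model is 2D with uniform radii, symmetric divisions, no apoptosis,
  no quiescence kinetics and no long-term negative feedback: it targets
  the first regenerative week.
* Signalling particles are not advected by tissue growth; the moving
  source strip is the only coupling from cells to signal.
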