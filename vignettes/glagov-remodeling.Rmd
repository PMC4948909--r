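---
title: "A three-layer morphoelastic model of arterial remodeling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-layer morphoelastic model of arterial remodeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`glagovsim` treats an atherosclerotic coronary artery cross-section as three
concentric, incompressible, hyperelastic annuli: intima, media and
adventitia, with unstressed radii `A < B < C < D`. The intima — the layer
that thickens in atherosclerosis — undergoes uniform, isotropic in-plane
growth; the media and adventitia do not grow but stretch elastically to
accommodate the expanding intima. The vessel remains a circular cylinder
throughout (axisymmetric, plane deformation, unit axial stretch), so the
entire state is described by the deformed radii `a < b < c < d`.

The kinematics follow the standard morphoelastic decomposition
`F = F_e F_g`: the growth tensor is `diag(g, g)` in the intima and the
identity outside, and incompressibility of the elastic part makes the radial
elastic stretch the reciprocal of the hoop stretch `alpha`. Integrating the
resulting map gives the deformed radius profile and, layer by layer, the
area-conservation identities

* plaque area `pi (b^2 - a^2) = g^2 pi (B^2 - A^2)` (the grown intima),
* `c^2 - b^2 = C^2 - B^2` and `d^2 - c^2 = D^2 - C^2` (media, adventitia),

so a single unknown — the deformed lumen radius `a` — determines everything
once `g` is known. Note one consequence that is easy to miss: the *elastic*
stretch jumps by exactly the factor `g` across the intima/media interface,
because the growth tensor is discontinuous there while the deformation map
is continuous. Radial *stress* is what must be (and is) continuous across
the interfaces.

Growth at constant volumetric rate `Gamma` gives `g(t) = exp(Gamma t / 2)`.
When curves are plotted against stenosis rather than time, `Gamma` cancels
completely; it only sets the clock. The package exploits this: trajectories
are computed on a geometric grid in `g` and time stamps are attached
afterwards.

### Constitutive description

The intima is Neo-Hookean with energy `mu1 (I1 - 3)` — deliberately *without*
the common `mu/2` prefactor, matching the convention in which the default
`mu1 = 5` kPa was calibrated. The media and adventitia use a
fiber-reinforced exponential (HGO-type) energy with a single symmetric fiber
family at angle `phi` to the hoop direction:

```
W_k = mu_k (I1 - 3) + (eta_k / beta_k) { exp(beta_k Q_k) - 1 },
Q_k = (1 - rho_k)(I1 - 3)^2 + rho_k (I4_k - 1)^2,
I4_k = alpha^2 cos^2 phi_k + sin^2 phi_k.
```

Defaults (kPa, degrees): media `mu = 1.27, eta = 21.60, beta = 8.21,
rho = 0.25, phi = 20.61`; adventitia `mu = 7.56, eta = 38.57, beta = 85.03,
rho = 0.55, phi = 67.0`; thicknesses 0.01 / 0.32 / 0.34 mm. Fiber angles are
stored in degrees as tabulated and converted to radians once, inside the
`fiber_reinforced()` constructor. Units are mm / kPa / years throughout;
pressures are accepted in mmHg and converted with 1 mmHg = 0.1333224 kPa.

The exponential term is ferociously stiff (`beta = 85.03` in the
adventitia): `exp(beta Q)` overflows double precision near hoop stretches of
~2.5, far below anything exotic. Equilibrium states of the model stay below
stretch ~1.7, so the constitutive evaluators carry a diagnostic *stretch
cap* (default 3): exceeding it raises an error rather than silently
returning `Inf`. The root solver intercepts that error during bracketing,
where transient excursions are expected, and treats it as "arbitrarily large
positive stress", which has the correct sign for the monotone residual.

## Solving for equilibrium

Quasi-static balance reduces, after eliminating the Lagrange multiplier and
integrating the radial equilibrium equation across the wall, to one scalar
equation in `a`: the luminal pressure must equal the sum of three layer
integrals of the radial-stress integrand. `pressure_residual()` evaluates
this in reference-frame variables; `residual_deformed_frame()` evaluates the
same balance in deformed-frame variables and is kept purely as a
cross-check (the two agree to the quadrature tolerance, and a property test
enforces this).

Two numerical choices matter here:

* **Closed-form Neo-Hookean integrals.** Under `u = R^2` the Neo-Hookean
  part of each layer integral is elementary
  (`mu [ln u - ln(m + s u) - m/(m + s u)]`). Only the fiber exponential term
  is integrated numerically (adaptive quadrature, relative tolerance 1e-10,
  per layer). This is not just speed: near lumen collapse `alpha^-4` in the
  0.01 mm intima spans ten decades and defeats adaptive quadrature, while
  the closed form is exact. A dense fixed-grid trapezoid evaluation of the
  full integrand is kept test-side as an independent oracle.
* **Bracketed root finding.** The residual is continuous and empirically
  strictly increasing in `a` (monotonicity can be asserted per solve via
  `solver_settings(check_monotone = TRUE)`, and the solver warns rather than
  silently picking a root if it fails). The bracket expands geometrically
  from `1.05 g A` — or from a warm start when walking along a trajectory —
  and the lower end walks down from the upper, staying on the finite branch
  between the collapsed-intima limit (residual `-Inf`) and the fiber
  overflow region (`+Inf`). Brent's method then refines to 1e-10 mm.

`stress_profile()` reconstructs `T_rr` across the wall from the deformed
anchors `T_rr(a) = -P` and `T_rr(d) = 0` and the hoop stress from
`T_theta = T_rr + alpha dW/dalpha`; interface continuity of `T_rr` and the
radial equilibrium ODE are verified by finite differences in the test suite
(the profile is diagnostic, not part of the solve).

## Remodeling curves, critical stenosis, compensation slope

`simulate_remodeling()` steps `g` geometrically (uniform in time) from 1,
re-solving equilibrium with pressure held fixed, and truncates at stenosis
0.9: beyond that the lumen has all but collapsed and the model — like any
purely mechanical, axisymmetric description — should not be trusted near
total occlusion. The default grid is 400 points; the upper `g` is estimated
from the area identities assuming the lumen holds its reference size, which
overshoots slightly and is then cut by the stenosis cap (typically ~310
solved states survive for the default geometry, about one second of compute).

The critical stenosis is the interior maximum of lumen area `L` against
stenosis `S`: `f'(S*) = 0`, `f''(S*) < 0`. `critical_stenosis()` takes the
grid argmax, requires it to sit at least two grid points from either end
(boundary maxima mean "monotone over the simulated range", not a critical
stenosis), and refines on a shape-preserving monotone cubic interpolant by
golden-section search between the two neighbouring grid points. Derivatives
are taken on the interpolant, never symbolically.

`compensation_slope()` regresses lumen area on plaque area over the early
trajectory. The default window is plaque area <= 0.5 mm^2; a stenosis-based
window (e.g. `stenosis_window = 0.2`, mimicking analyses restricted to
mildly stenotic samples) is exposed as an alternative, since historical
analyses windowed on stenosis rather than plaque burden.

Ex-vivo (unpressurized, post-mortem) states are obtained by solving with
`P = 0` at the same `g` as an in-vivo state. Because growth in this model is
stress-independent, that is identical to simulating the whole history at
`P = 0`; the test suite asserts this equivalence (via growth-rate invariance
and pressure-matched comparisons) rather than assuming it.
`exvivo_invivo_table()` reports the qualitative contrast at matched growth:
depressurization shrinks IEL and lumen, leaves plaque area exactly unchanged
(incompressibility), and therefore raises the measured stenosis.

With the default parameter set the simulated ex-vivo curves are non-monotone
— the compliant outer layers first dilate, then the exponentially stiffening
collagen fibers lock the vessel and force inward remodeling — with the
interior maximum between roughly 16% and 20% stenosis across initial lumen
areas 5–15 mm^2, and an early-stage compensation slope between about +2.2
and +2.7 mm^2 of lumen per mm^2 of plaque (both recomputed by the test suite
and the acceptance script). Pressurized (in-vivo) curves at 50–110 mmHg are
monotone decreasing: no critical stenosis. The default initial lumen area,
where one must be chosen, is 12 mm^2.

## Penalized smoothing splines

`fit_smoothing_spline()` minimizes, over natural cubic splines with knots at
the data sites,

```
k * sum_i (l_i - L(s_i))^2  +  (1 - k) * integral (L''(S))^2 dS,
```

with the integral over the span of the stenosis values. Two documented
readings are built in. First, the curvature integral is taken over the
stenosis range (the natural reading; the integrand is `d^2 L / dS^2`, so
limits in lumen-area units would be dimensionally inconsistent). Second, the
`(k, 1-k)` weighting is implemented exactly as written — no
reparameterization onto any external tool's smoothing scale — so `k = 0` is
the least-squares straight line, `k = 1` the natural interpolating spline,
and everything in between solves the Reinsch system
`(R + (1-k)/k Q'Q) gamma = Q' l` for the knot second derivatives. Natural
(zero second derivative) boundary conditions are the unconstrained-minimum
conditions for this objective. Duplicated stenosis values are averaged with
a warning; `k` outside `[0, 1]` is rejected.

One practical consequence of the exact weighting: on dense data the two
terms have very different scales, and the interesting transition happens
close to `k = 1`. The default `k_sweep()` grid is therefore log-spaced in
`1 - k` (`k = 0, 0.9, 0.99, ..., 1 - 1e-8, 1`). `interior_maximum()` finds
stationary points from the analytic piecewise-quadratic derivative of the
fitted spline, keeps those with negative curvature strictly inside the data
span, and reports the one with the largest fitted value (rough
near-interpolating fits can have several).

The implementation is validated two ways: the banded solve against direct
numerical minimization of the objective over knot values (on small point
sets, BFGS from the data), and the `k -> 0` / `k -> 1` limits against
`lm()` and exact interpolation.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure of histology-style
point clouds: many vessels, each observed *once* at an unknown disease
stage. Per vessel it draws an initial lumen area, a growth rate and an
observation time, grows the model to that time (warm-started equilibrium
solves along a geometric ladder in `g`), and records the observed
`(stenosis, lumen area)` pair with additive Gaussian noise on the area.
Defaults, chosen once as plausible study conditions:

* 150 vessels; initial areas uniform on 5–15 mm^2 (the range of the
  reference simulations);
* growth rate log-normal with median 0.5 /year and log-SD 0.3 — plaque
  progression is highly variable across patients, and a right-skewed
  positive distribution is the standard minimal model of that variability;
* observation time uniform on 0–14 years, which spreads observed stenoses
  over roughly 0.01–0.85 for these growth rates;
* lumen-area noise SD 1 mm^2 (of order 5–10% of a healthy lumen, a
  reasonable figure for planimetry on sections);
* observations truncated at stenosis 0.85 (the model is not trusted near
  occlusion); the in-vivo preset additionally redraws observation times
  until stenosis >= 0.10, mimicking older clinical cohorts with essentially
  no early-stage plaques, and draws a per-vessel pressure uniform on 50–110
  mmHg.

All draws flow from a single generator seeded in the `cohort_spec()`, so a
cohort is reproducible from its spec alone. Per-vessel ground truth (true
lumen area, growth factor, rate) is retained for recovery tests.

What the generator does *not* emulate — and therefore what passing recovery
tests do and do not show: eccentric plaques, measurement error on stenosis
itself, vessel-wall parameter heterogeneity, tapering, and any biological
feedback (shear-stress response, vasodilation, media atrophy). A recovered
critical stenosis on synthetic cohorts demonstrates that the spline
workflow can extract the model's interior maximum from single-observation
noisy cross-sections; it says nothing about whether real arteries follow
this model.

The end-to-end recovery check fits the default `k_sweep()` grid to an
ex-vivo cohort and compares the *median* interior-maximum location across
the k values where one exists against the mean critical stenosis of the
generating model (averaged over initial areas 5, 8, 12, 15 mm^2). The
median-over-sweep statistic was fixed at design time: single-`k` locations
wander by a few percentage points with noise, and the sweep median is a
robust summary of where the maximum emerges.

## Numerical summary

| Quantity | Value |
|---|---|
| Quadrature (fiber terms) | adaptive, rel. tol 1e-10 per layer |
| Root tolerance on `a` | 1e-10 mm (Brent) |
| Trajectory grid | 400 geometric `g` points, truncated at stenosis 0.9 |
| Critical-stenosis refinement | monotone cubic + golden section, tol 1e-10 |
| Frame-equivalence check | 1e-6 kPa |
| Plaque-area pressure invariance | 1e-10 relative |
| Stretch cap (exponential path) | 3 (diagnostic error above) |
| Cohort used in recovery tests | 150 vessels, noise SD 1 mm^2 |

The full test suite (including four 400-point ex-vivo curves, three in-vivo
curves and the 150-vessel recovery cohort) runs in well under a minute on a
single core.

## Known limitations

* Axisymmetric, concentric plaques only; no eccentric morphology.
* Purely mechanical: no shear-stress endothelial response, vasodilation or
  media atrophy; growth is stress-independent, so ex-vivo histories and
  depressurized in-vivo states coincide by construction.
* The intima stays Neo-Hookean with fixed `mu1` even as real plaques
  stiffen and fibrose; the default `mu1 = 5` kPa is deliberately compliant.
* Uniqueness of the equilibrium root is asserted empirically (optional
  monotonicity probe), not proven; the solver warns if it detects
  non-monotonicity across the bracket.
* Near-occlusion states (stenosis > 0.9) are outside the trusted range and
  are truncated everywhere.
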