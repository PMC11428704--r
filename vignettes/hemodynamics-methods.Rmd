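---
title: "Methods: pulsatile vessel hemodynamics and wall shear stress indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pulsatile vessel hemodynamics and wall shear stress indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemoflow)
```

## Scope and model

`hemoflow` is a desk-scale analogue of the patient-specific CFD workflow
used to study aortic aneurysm and dissection: geometry, pulsatile flow,
wall shear stress (WSS), and the four endothelial risk indices TAWSS,
OSI, RRT and ECAP. Patient CT anatomy is replaced by parameterized
synthetic domains — an (optionally tapered) straight tube, a curved arch
channel, and a dissected two-lumen channel in which an impermeable septum
separates a true and a false lumen that communicate only through intimal
tears. The dissected topology mirrors the clinical situation: the false
lumen is sealed at the inlet and is perfused exclusively through the
entry tear, while both lumens discharge at the outlet.

Blood is an incompressible generalized-Newtonian fluid with the
Carreau–Yasuda law
$$\mu(\dot\gamma) = \mu_\infty + (\mu_0 - \mu_\infty)
  \bigl[1 + (\lambda\dot\gamma)^2\bigr]^{(n-1)/2},$$
where $\dot\gamma = \sqrt{2\,D\!:\!D}$ is computed from the
rate-of-deformation tensor. The exponent is $(n-1)/2$: with $n < 1$ this
is the only sign for which the high-shear limit tends to the *infinite
shear* plateau $\mu_\infty$, which fixes an ambiguity in how the law is
sometimes typeset. Defaults (density 1060 kg/m³, $\mu_\infty$ = 0.0035
Pa·s, $\mu_0$ = 0.056 Pa·s, $\lambda$ = 3.313 s, $n$ = 0.3568) live in
`inst/defaults/defaults.yaml` together with every other physiological
constant the package assumes.

The solver runs in the laminar regime. Clinical aortic solvers typically
wrap the same momentum equations in a k–ω SST turbulence closure; at the
Reynolds numbers of our desk-scale domains that transport system is not
warranted, so it is deliberately not solved. The *algebraic* pieces of
the closure that are well defined pointwise — the blending function
$F_2 = \tanh(\mathrm{arg}_2^2)$ with
$\mathrm{arg}_2 = \max\!\bigl(2\sqrt{k}/(\beta^*\omega d),\;
500\nu/(\omega d^2)\bigr)$, the eddy viscosity
$\mu_t = a_1\rho k / \max(a_1\omega, S F_2)$, and the Boussinesq stress
tensor — are exposed as pure functions so they are testable in
isolation. The constants $a_1 = 0.31$ and $\beta^* = 0.09$ are the
standard SST literature values.

## Discretization

The solver uses a staggered (MAC) structured grid of square cells with a
fluid mask: face-normal velocities on faces, pressure at cell centres.
Axisymmetric tubes carry the metric weights $r$ of a body of revolution
(the symmetry axis contributes zero-area faces, which removes the
coordinate singularity without special-casing); planar channels use unit
weights. Curved or tapered walls are stair-stepped by the mask. Each time
step is an explicit predictor (advective-form convection, first-order
upwind by default with an optional 90 % central blend; stress-divergence
diffusion with the viscosity lagged one Picard iteration) followed by an
exact pressure projection: the Poisson matrix is assembled once, factored
with a sparse Cholesky decomposition, and reused every step. Because the
projection enforces the discrete divergence exactly, the net boundary
flux of every converged state sits at round-off (the suite asserts
< 1e-8 relative; observed values are ~1e-15).

Boundary conditions: prescribed inlet velocity profiles (flat, parabolic,
or a fully developed Womersley profile reconstructed from the waveform's
harmonics) or a prescribed inlet pressure; prescribed outlet pressure
with zero tangential stress; no-slip rigid walls. The no-slip diffusion
flux at a wall uses a quadratic ghost through the wall (exact for
parabolic profiles, falling back to linear reflection in single-cell
passages). This choice was made after measuring the linear-reflection
ghost at only first-order wall-flux accuracy, which broke the
monotonicity of the Poiseuille WSS refinement ladder; with the quadratic
ghost the ladder converges at second order.

Wall shear stress is extracted per wall face as
$\tau_w = \mu(|\partial u_t/\partial n|)\,\partial u_t/\partial n$ with
the one-sided quadratic fit $(9u_1 - u_2)/(3h)$ through the wall and the
first two cell centres — again exact for parabolic profiles, so the
steady-tube extraction inherits the solver's second-order accuracy. The
sign of $\tau_w$ encodes direction along the wall tangent, which is what
OSI needs.

Residuals follow the single scalar tolerance convention (default
$10^{-5}$) applied to momentum and continuity alike: for steady marches
the residual is the pseudo-time velocity change scaled by
$L/(\Delta t\,U^2)$; for transient steps it is the maximum of the scaled
continuity residual and the Picard iteration change. Exceeding the
stability limits raises a typed error carrying a suggested time step;
non-convergence raises a typed error carrying the residual history.
Transient runs march a configurable number of cycles (default 3) and
report the final one; the cycle-to-cycle drift of mean pressure is
recorded and warned about above 1 %.

## Index quadrature and degeneracies

A `wss_series` samples one period uniformly at $t_k = kT/n$; on that
periodic grid the trapezoidal rule equals the plain sample mean, which is
exact for piecewise-linear periodic integrands — this makes the square
-wave endpoint cases (OSI exactly 0 and exactly 0.5) hold to machine
precision on even grids. The OSI denominator is the magnitude integral
$\int |WSS|\,dt$, the standard normalization that guarantees
OSI $\in [0, 0.5]$; the $1/T$ factors cancel. Points with zero magnitude
integral take OSI = 0 by definition. RRT is singular where OSI → 0.5 or
TAWSS → 0; such points are capped at a configurable ceiling (default
$10^3$ 1/Pa, roughly three decades above the values a 2–6 Pa TAWSS
produces) and flagged `degenerate` instead of becoming infinities; ECAP
flags zero-TAWSS points the same way. Everywhere unflagged the algebraic
identities RRT·TAWSS·(1 − 2·OSI) = 1 and ECAP·TAWSS = OSI hold exactly
and are property-tested.

## Waveforms

The literature waveforms that drive patient-specific runs are not
reproducible here, so pulses come from a constrained family: a truncated
cosine series about the systolic peak time with geometrically decaying
positive amplitudes, rescaled so the sampled waveform attains the
systolic level exactly at the peak time and the diastolic level at its
minimum. Positivity of the amplitudes guarantees the global maximum sits
exactly on the peak; an optional seed jitters the harmonic amplitudes to
produce distinct but equally valid family members. Defaults: 1 s period,
peak at 0.14 s, 140/80 mmHg pressure envelope, 8 harmonics. The family is
symmetric about the peak — it does not reproduce the anacrotic/dicrotic
asymmetry of measured pulses, which is irrelevant to the quantities the
package computes but worth knowing before visual comparison with clinical
traces.

The waveform-comparison metric is the reference-normalized relative L2
difference in percent (a symmetric variant is available). This is a
definitional choice: published "percent difference" figures for waveform
validation rarely state their metric, so the package states its own
prominently. Systolic metrics report the percent amplification of the
test maximum over the reference maximum and the peak lead measured with
parabolic sub-sample refinement, matching the 0.01 s reporting
resolution common in the field. 1 mmHg = 133.322 Pa everywhere; all
internal computation is SI and unit tags are enforced at the boundaries.

The Womersley oracle (complex Bessel series; $J_0, J_1$ of complex
argument implemented as ascending power series, valid for Womersley
numbers up to ~17 in double precision) provides the analytic transient
benchmark. Its test comparison is deliberately non-circular: the solver
case is driven by an oscillating inlet/outlet *pressure difference*, and
the tests additionally pin the series implementation against an
independent finite-difference harmonic boundary-value solve that uses no
Bessel functions.

## Synthetic generators

`make_wss_series()` composes, per wall point, a steady component $a$ plus
an equal-dwell reversing square wave of amplitude $b$ along a random unit
direction. For $b \ge a \ge 0$ the continuous-time indices are closed
form — TAWSS $= b$, OSI $= (1 - a/b)/2$ — so the generator inverts the
targets exactly ($b$ = target TAWSS, $a = b(1 - 2\,\mathrm{OSI})$). A
square wave rather than a sinusoid is used precisely because this
inversion is exact, which turns index testing into a round trip with no
quadrature caveats on even grids. `make_pressure_pair()` scales a base
pulse about its diastolic floor to hit a prescribed systolic
amplification exactly and applies a periodic time shift for the peak
lead; the presets exercise the false-lumen (25 %, 0.01 s lead) and
true-lumen (3 %) comparison structure. Noise injection is additive
Gaussian scaled by the signal RMS — the simplest model that exercises
estimator robustness; it makes no claim of physiological realism, and
passing recovery tests therefore demonstrates estimator correctness and
stability, not performance on measured clinical waveforms.

## Problem sizes and solver scope

The shipped tests and fixtures use sizes chosen for a single CPU:
Poiseuille ladder at 8/16/32 cells across a 20 mm diameter (Re ≈ 30,
elevated Newtonian viscosity 0.035 Pa·s so the steady march settles
quickly), a 2 mm-radius Womersley tube at Womersley number 2.8 with a
0.2 ms step over three cycles, and a 60 mm dissected channel with full
blood rheology over three cycles. These are the package's reference
conditions; all tolerances (2 % steady WSS, 3 % transient L2, 1 % /
0.005 index recovery) are met at these sizes and tighten under
refinement.

The flow solver requires grid-aligned inlet and outlet boundaries, so it
accepts straight (axisymmetric or planar) and dissected planar meshes.
The curved arch geometry is fully supported for mesh generation,
refinement, validity audit and VTK export, but `solve_*` rejects it: a
body-fitted or cut-cell treatment of angled in/outflow planes would be
needed for trustworthy fluxes there, and a stair-stepped approximation
would undermine the conservation guarantees the package advertises.
This is a deliberate scope boundary, not an oversight.

Other known limitations: 2-D planar/axisymmetric only (no secondary
flow/Dean vortices, no 3-D helicity); rigid walls (no fluid–structure
interaction — the clinical workflow this mirrors also assumes rigid
walls); no turbulence transport; first-order upwind advection unless the
central blend is selected; stair-step wall representation for tapered and
curved boundaries, where WSS extraction falls back to first order. Wall
Y+ is reported as a diagnostic; no target threshold is enforced because
the laminar 2-D grids here have no equivalent of the near-wall resolution
criteria used by wall-modelled turbulent solvers — resolution guidance is
simply "refine until the convergence report's relative changes are
acceptable".

## Reproducibility

All randomness (waveform jitter, synthetic directions, noise) flows
through explicit integer seeds; the solver itself is deterministic, and
identical configurations produce bitwise-identical artifact bundles. The
run summary (`summary.json`) is the stable machine interface and is
checked against the shipped structural schema.
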