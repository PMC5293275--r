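---
title: "An immersed-boundary model of glioma cell infiltration through narrow intercellular gaps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An immersed-boundary model of glioma cell infiltration through narrow intercellular gaps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliomaIB)
```

## The model

Invading glioma cells migrate through brain tissue whose intercellular
spaces are often narrower than the cell's own nucleus. Passage then requires
active, myosin II-dependent softening and deformation of the nucleus:
knocking myosin II down leaves the nucleus stiff and the cell stuck at the
gap. `gliomaIB` implements a two-dimensional multiscale model of this
process with four coupled layers.

**Fluid–structure mechanics.** All cells are immersed in a viscous
incompressible fluid on a doubly periodic square box, solved spectrally.
Per time step the solver applies the Lagrangian boundary forces spread onto
the grid, projects onto divergence-free fields (the multiplier is the
pressure, in a zero-mean gauge), and integrates each viscous Fourier mode
exactly:

$$\rho\left(\partial_t \mathbf u + \mathbf u\cdot\nabla\mathbf u\right)
  = -\nabla p + \mu\Delta\mathbf u + \mathbf f, \qquad
  \nabla\cdot\mathbf u = 0 .$$

A glioma cell is two closed elastic curves — membrane and nucleus — and
each normal glial cell is a single closed curve tethered node-by-node to
fixed tissue anchors. Curves carry Hookean stretching energy
$E = \tfrac c2\int |\partial_s \mathbf X|^2\,ds$ (zero rest-length springs,
so closed curves are pre-tensioned; their contraction is balanced by
tethers and fluid incompressibility). Forces are spread to the grid and
velocities interpolated back with the standard 4-point immersed-boundary
kernel, whose discrete moment conditions make the two operations exact
adjoints; structures move at the local fluid velocity (no-slip).

**Migration cycle.** Motion is a two-phase amoeboid cycle. During
*elongation* the rear arc of the membrane is tethered to anchors frozen at
the phase switch and the front arc carries an active force density
$c_a\vec d$; during *retraction* the active force is off, the rear is
released, and the front arc is tethered to anchors frozen at the switch, so
membrane tension pulls the cell body and nucleus forward. Switching is
driven by the smoothed rate of change $L'(t)$ of the cell-body length:
elongation ends when $L'$ decays to the retention rate
$\delta_{ret}^+ > 0$, retraction ends when $L'$ recovers to
$\delta_{ret}^- < 0$, and either phase times out at a configurable maximum
duration. The direction $\vec d$ is the normalized disk average of the
chemoattractant gradient within the chemotactic sensing radius.

**Chemoattractant.** A single source injects chemoattractant at rate
$\lambda_{in}^C$ on a small disk; the field diffuses ($D_C$), decays
($\mu_C$) and obeys no-flux boundaries. The active force constant is
$c_a = \chi(\alpha + |F_C|)$ with the saturating gradient response
$F_C = \nabla C / (1 + \lambda_s |\nabla C|^2)$, which is bounded by
$1/(2\sqrt{\lambda_s})$ no matter how steep the gradient.

**Acto-myosin control of the nucleus.** Each membrane point senses the
disk-averaged fluid pressure (radius $R_s$); the membrane average $p^s$
sets the available actin concentration $[a] = k_p\,p^s$ (clamped at zero —
the zero-mean pressure gauge can make unconfined readings slightly
negative). Bound myosin II follows mass-action kinetics
$$\frac{d[m_b]}{dt} = k_1 [m_T][a] - (k_1 [a] + k_{-1})[m_b],$$
with steady state $[m_b]_s = [m_T][a]/([a] + 1/K)$, $K = k_1/k_{-1}$. The
nucleus stiffness is $c_e^{Gn} = c_e^{Gn,b}\, r([m_b])$ with the Hill-type
stiffening rate
$$r([m_b]) = \frac{k_s\,(1/[m_b])^n}{K_{mb}^n + (1/[m_b])^n} + k_s^{min},$$
monotone decreasing from $k_s + k_s^{min}$ (no bound myosin: stiff nucleus)
to $k_s^{min}$ (saturated: soft nucleus), with half maximum at
$1/[m_b] = K_{mb}$. Confinement therefore closes the loop: pressure rises at
a gap, actin and bound myosin accumulate, the nucleus softens and can be
squeezed through. The myosin knockdown (MYOII-KD) is modeled solely as the
20-fold reduction of $k_p$ (0.9 to 0.045).

**Drugs.** Two pulsed anti-invasion schedules force the kinetics:
blebbistatin $B(t)$ adds a capping term $-\alpha B [m_b]$, and an
association inhibitor $D(t)$ attenuates the binding rate by $e^{-D}$. Both
follow $dX/dt = \sum_j I\,[t_j \le t < t_j + \tau_p] - \mu X$ with pulse
length $\tau_p$ (default 1/3 h) at the start of each dosing cycle. All
kinetic updates use exact exponential integration of the coefficient-frozen
linear ODEs, so no solver tolerance enters the model.

## Parameters

`scenario_config()` defaults to the published CGS parameter set: a
0.1 mm × 0.1 mm box on a 512² grid with dt = 0.004 s; fluid density
1.35 g/cm³ and viscosity 2.7 g/(cm·s); glioma radius 5 µm (nucleus 3 µm by
default — the nucleus size is a free choice, set so that scenario gaps are
narrower than the nuclear diameter), membrane stiffness 3.8e-5 g·cm/s²,
basal nucleus stiffness 3.8e-5, normal-cell stiffness 2.3e-3, tether
stiffnesses 1500 (glioma) and 400 (normal) g/(cm·s²); χ = 0.7, α = 0.15,
λ_s = 20; sensing radii 4.69 µm (pressure) and 0.4 µm (chemotaxis);
k₁ = 0.002 µM⁻¹s⁻¹, k₋₁ = 1e-4 s⁻¹, [m_T] = 1 µM, n = 10, K_mb = 1.8 µM⁻¹,
k_s = 5, k_s^min = 0.1; D_C = 2.15e-6 cm²/s, λ_in^C = 0.82, μ_C = 1e-6 s⁻¹;
I_B = 5e-2 µM/s, μ_B = μ_D = 5.13e-4 s⁻¹, α = 1e-4 s⁻¹µM⁻¹.

Parameters the underlying description leaves open are exposed with
documented defaults: the nucleus radius (0.6 of the cell radius), the
front/rear arcs (±60° about the migration direction), the retention rates
(±0.02 µm/s with a 120 s phase timeout, calibrated so the free-space cycle
period is about two minutes), the drug pulse length (1/3 h), the
chemoattractant source radius (one grid cell), and an overall
`pressure_scale` calibration constant on the sensed pressure (the pressure
gauge fixes only the spatial mean, so the scale entering $k_p p^s$ is a
configuration quantity).

## Numerical choices

* **Fluid solver.** Fourier collocation; advection in skew-symmetric form,
  explicit; the Leray projection uses the derivative-consistent spectral
  symbol so the discrete divergence vanishes to machine precision; each
  viscous mode is advanced with its exact exponential factor, which is
  unconditionally stable and remains correct in the overdamped (Stokes)
  regime the cell-scale parameters live in. The spatial-mean force mode is
  removed by default (momentum gauge) so the periodic box does not drift;
  an option retains it, in which case the mean velocity follows the exact
  k = 0 ODE.
* **Chemoattractant.** Cell-centered grid; backward-Euler diffusion with
  the 5-point Neumann Laplacian diagonalized exactly by a DCT-II (via FFT
  of the even extension). The implicit operator is an M-matrix, so
  non-negativity is preserved; source and decay are combined in their exact
  per-step update, so total mass obeys its balance ODE to machine
  precision.
* **Stability.** `stability_dt()` caps the configured step with the
  advective CFL bound and heuristic relaxation-rate bounds for the
  explicitly coupled elastic (rate ≈ c/(µ ds)) and tether (rate ≈ ct ds/µ)
  forces; the runner sub-steps the fluid–structure update when required.
* **Degenerate inputs.** Coincident curve nodes error; a flat
  chemoattractant field retains the previous migration direction; negative
  sensed pressure clamps the actin concentration at zero; bound myosin is
  clamped to [0, m_T] (the exact updates preserve this for non-negative
  actin anyway).

## Reduced-scale fixtures and what they show

The published headline runs (512² grid, hours of simulated time at
dt = 0.004 s) are long-running by design. The test suite and the
acceptance script instead exercise the full coupled machinery on
*scaled-mode* fixtures (`fixture_generator()`), chosen once as the
package's reduced study conditions:

* 64² (and 128²) grids on the same 0.1 mm box; dt = 0.05 s; lower
  viscosity (0.15 g/(cm·s)) so the overdamped flow responds on the second
  scale; advection off (the cell-scale Reynolds number is ~1e-6, so the
  term is physically negligible);
* a 10 µm glioma cell with a 5 µm nucleus facing a 6 µm gap between two
  16 µm tethered normal cells — the gap is 0.6 of the nuclear diameter,
  preserving the defining geometric obstruction;
* membrane/nucleus stiffnesses, kinetic rates (k₁ = 0.1, k₋₁ = 0.005,
  preserving K = 20), phase clocks and the pressure-scale constant rescaled
  together so that an elongation–retraction cycle lasts seconds rather than
  minutes and bound myosin equilibrates within the run. The calibration was
  fixed once during development and is not adjusted per experiment.

Under these conditions the wild-type cell (k_p = 0.9) softens its nucleus
(stiffening rate falls from 5.1 toward 0.1) and completes gap passage
within the 500 s horizon, while the MYOII-KD cell (k_p = 0.045) keeps a
high stiffening rate, a nearly undeformed nucleus (lateral deformation
ratio near 1), and stalls below the gap — the model's central mechanism at
reduced scale. The 64² and 128² fixtures agree on this classification.

What the scaled fixtures do **not** show: quantitative speeds or passing
times comparable to the published full-scale values (those require the 512²
configuration, which `scenario_config()` provides as the default), membrane
resolution effects at the published node density, and any effect of the
advection term. Real tissue features outside the model — cell–cell
adhesion, ECM proteolysis, three-dimensional geometry, stochastic
protrusion dynamics — are out of scope regardless of scale.

## Known limitations

* The fluid is periodic while the chemoattractant is no-flux on the same
  box; the mismatch is inherited from the model description and is
  harmless away from the walls.
* Zero rest-length membranes mean "resting" shapes are balances of
  pre-tension, tethering and incompressibility rather than stress-free
  circles; stiffness values are therefore not directly comparable to
  membrane elastic moduli.
* Immersed-boundary coupling leaks a small amount of enclosed area over
  long runs (the suite bounds it below 1% per 10,000 coupled steps).
* The pass/block classification depends on a gap-line coordinate supplied
  by the scenario geometry; for non-vertical migration it should be read
  as the coordinate along the gap axis.

## A worked example

```{r example, eval = FALSE}
library(gliomaIB)

wt <- run_simulation(build_scenario(fixture_generator("mini_two_gap")))
kd <- run_simulation(build_scenario(fixture_generator("mini_two_gap_kd")))

classify_passing(wt$trace, gap_line_y = 0.005)  # passed, with passing time
classify_passing(kd$trace, gap_line_y = 0.005)  # blocked at the gap

min(wt$trace$Lperp)   # strong lateral nucleus squeeze
min(kd$trace$Lperp)   # nucleus stays nearly round
range(wt$trace$r)     # stiffening rate drops toward k_s^min
tail(kd$trace$r, 1)   # remains near k_s + k_s^min
```

Sweeps over drug dose grids, astrocyte separations, nucleus stiffness
folds or source strengths use `run_sweep()` over dot-separated
configuration paths, e.g.
`run_sweep(cfg, axes = list(`normals.d` = c(3, 4, 5, 6) * 1e-4))`.
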