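---
title: "Centrifugal microfluidic emulsification: models and numerics"
author: "spindrop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centrifugal microfluidic emulsification: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spindrop)
```

## The physical problem

A lab-on-a-disc emulsifier generates water-in-oil droplets without
external pumps: the disc's rotation pumps the continuous phase (silicone
oil) down a radial channel; at T-junctions fed from cell reservoirs the
dispersed phase (an aqueous cell suspension, modelled as water) is
sheared into droplets inside circumferential sub-channels; a downstream
bifurcated junction separates the droplets from the oil using the
balance of centrifugal and Coriolis pseudo-forces. `spindrop` implements
this system twice over, at two levels of description:

1. **Dimensionless design rules.** The capillary number
   $Ca_{CP} = \eta_{CP} V_{CP} / \sigma$ and Weber number
   $We_{DP} = \rho_{DP} L V_{DP}^2 / \sigma$ locate the
   dripping-to-jetting transition; the rotational Bond number
   $Bo = |\Delta\rho|\, r\, \Omega^2 L^2 / \sigma$ measures centrifugal
   versus interfacial effects on droplet formation; the centrifugal
   pumping velocity $U = D_h^2 \rho \Omega^2 \bar r \,\Delta r /(32 \eta c)$
   sets the feed; and the Rossby number $Ro = \rho \Omega D_h^2/\eta$
   (obtained from $2\Omega U/\Omega^2 r$ with the pumping estimate for
   $U$ and the liquid column's radial extent equal to its length)
   governs which outlet a phase selects at the separation junction:
   outlet A (radially outward) for $Ro < 1$, outlet B (lateral) for
   $Ro > 1$.
2. **A planar two-phase volume-of-fluid (VOF) solver** in the
   co-rotating frame, which resolves droplet formation, transport,
   merging and outlet selection on the rasterized channel network.

The built-in fixtures carry the study's operating values: 200 × 100 µm
channels ($D_h = 133.3$ µm) on a 108 mm disc, silicone oil
(64.3 cP, 908.7 kg/m³) with water (1.003 cP, 997 kg/m³),
$\sigma = 14.26$ mN/m, PDMS contact angles of 112° (water) and 26.44°
(oil), rotation up to 150 rad/s; and, for the rotating flow-focusing
benchmark, sunflower oil (62.2 cP, 909 kg/m³) with water (1.09 cP,
1005 kg/m³), $\sigma = 28.33$ mN/m, a 25 mm × 660 µm × 200 µm droplet
channel with a 376 µm constriction and an 80° junction at 24 or 40 Hz.

### Why the Rossby number is evaluated per phase

The separation argument compares Coriolis to centrifugal effects *for
the moving liquid*, and the two phases differ a hundred-fold in
viscosity. Evaluating $Ro$ with each phase's own density and viscosity
is what reproduces the separation: water gives $Ro = 2.65$ at
150 rad/s (outlet B — the droplets), silicone oil $Ro = 0.038$ (outlet
A — the continuous stream). A single mixture-valued $Ro$ would erase
exactly the contrast the junction exploits.

## Governing equations and discretization

The solver advances the incompressible two-phase equations in the
rotating frame: volume-fraction transport
$\partial_t \alpha_{CP} + V\cdot\nabla\alpha_{CP} = 0$, continuity, and
momentum with mixture properties
$\rho = \alpha_{CP}\rho_{CP} + (1-\alpha_{CP})\rho_{DP}$ (likewise
$\eta$), a continuum-surface-force (CSF) interfacial term, and the
body acceleration
$S = -\Omega\times(\Omega\times r) - 2\Omega\times V - \dot\Omega\times r$
(centrifugal, Coriolis, Euler; the Euler term is written
$-\dot\Omega\times r$, identical by antisymmetry to the equivalent
$r\times\dot\Omega$ form). Gravity is neglected: the disc plane is
horizontal and the films are thin.

Discretization choices, in the order they matter:

* **Staggered (MAC) grid.** Face-normal velocities make the discrete
  divergence exact; after each projection the divergence is at solver
  precision (the regression suite checks $<10^{-8}$ s⁻¹).
* **Planar-2D with out-of-plane friction.** The simulation plane is the
  disc plane. The finite depth $H$ enters through a Hele-Shaw drag
  $-12\eta V/H^2$ in momentum and through volume reconstruction in the
  droplet metrics (volume = in-plane area × $H$). A full-3D interface
  is not represented; consequences are discussed under *Limitations*.
* **PLIC interface.** Youngs-type normals from a renormalized smoothed
  volume fraction; the line offset in each mixed cell is solved in
  closed form so the cut area reproduces $\alpha$ to $10^{-10}$.
  Advection uses direction-split geometric PLIC fluxes with the fixed
  divergence correction that keeps the scheme exactly conservative and
  bounded for divergence-free velocities (sub-cycled to per-sweep
  Courant $\le 0.45$; sweep order alternates).
* **Balanced-force CSF.** The printed form of the interfacial term in
  the source study is typographically garbled; the standard
  density-weighted CSF form
  $f = \sigma\kappa\nabla\alpha_{CP}\,\rho/\tfrac12(\rho_{CP}+\rho_{DP})$
  is used, applied as a face acceleration
  $\sigma\kappa_f\nabla_f\alpha/\tfrac12(\rho_{CP}+\rho_{DP})$ so that a
  static interface is balanced by the discrete pressure gradient.
  Curvature is the smoothed-gradient divergence with
  interface-weighted averaging (two passes); this combination passes
  the static-droplet gate (Laplace pressure within 5% at
  $\Delta x = R/20$, measured ~2%).
* **Contact angles.** The static angle enters twice: PLIC normals in
  wall-adjacent mixed cells are rotated to
  $\hat n = \hat n_{wall}\cos\theta + \hat t_{wall}\sin\theta$, and in
  the curvature stencil the wall-face component of the interface
  normal is prescribed as $-\cos\theta$ toward the solid. A droplet
  seeded on a wall then relaxes toward its equilibrium cap from either
  side (hydrophobic angles retract the contact line, wetting angles
  spread it); contact-line motion relies on the implicit numerical
  slip of the cell-scale no-slip wall, so relaxation is slow compared
  with bulk capillary dynamics.
* **Projection with a constant-coefficient Poisson operator.** The
  pressure operator uses a fixed reference density
  $\rho_0 = \tfrac12(\rho_{CP}+\rho_{DP})$ and is Cholesky-factorized
  once per grid; buoyancy is retained by weighting the body
  acceleration with $\rho/\rho_0$ (Boussinesq treatment). Both working
  fluid pairs have density ratios of ~1.1, well inside the regime
  where this is accurate; it buys an order of magnitude in runtime.
  Two PISO-style correction sweeps are performed per step.
* **Implicit viscosity.** The viscous term $\nabla\cdot(\eta\nabla V)$
  (the transpose part of the stress is dropped, a standard
  simplification for near-uniform-viscosity regions) plus the
  Hele-Shaw drag are solved implicitly per velocity component, reusing
  the symbolic Cholesky factorization across steps. This removes the
  explicit viscous time-step limit, which would otherwise dominate for
  64 cP oil.
* **Momentum advection** is second-order central where the stencil
  stays in fluid (cell Péclet numbers here are well below the central
  stability bound) and first-order upwind beside walls.
* **Time step** $\Delta t = \min(\mathrm{CFL}\,\Delta x/|V|_{max},\;
  0.7\sqrt{(\rho_{CP}+\rho_{DP})\Delta x^3/4\pi\sigma},\; \Delta t_{max})$:
  the capillary bound governs two-phase runs. A strict mode fixes
  $\Delta t = 10^{-7}$ s, the reference configuration of the original
  study; default runs use the adaptive bound.
* **Boundary conditions.** No-slip walls, fixed inlet velocities
  (either given directly or derived from the centrifugal pumping
  formula; fixed values on rotating cases ramp with $\Omega(t)^2$ to
  emulate pumping during spin-up), zero-gauge pressure and
  zero-gradient volume fraction at outlets, with re-entrant outlet
  flow clamped to zero (logged once). The domain starts filled with
  continuous phase at rest; dispersed feed channels are primed with
  dispersed phase up to the junction mouth, as a filled feed line
  would be.

## What the synthetic cases emulate — and what they do not

Every input is constructed in-package from published operating values:
fluid properties, geometry, rotation schedules (linear spin-up over
10 ms by default — the source study does not state its ramp), and
verification toys (static droplet, translated patch, slotted-disc
rotation, rotating channel with expansion, Poiseuille channel). The
spin-up ramp, the inlet velocities (the study specifies velocity inlets
but not their values; defaults are chosen from the centrifugal pumping
scale and the dripping window), and the radial station of the
flow-focusing junction (default 32 mm, the one radial station the study
prints) are documented free parameters.

Passing the verification suite demonstrates correct interfacial
statics, exact volume conservation, correct single-phase rotating-frame
hydrodynamics and mesh-converged profiles. It does **not** demonstrate
quantitative 3D droplet morphology: the planar model cannot represent
the depth-direction meniscus or the Ekman-type secondary flow, so
droplet sizes and generation rates from planar runs are scaled-down
analogs, compared with the published populations in direction and
order of magnitude only.

Two planar-2D consequences deserve emphasis:

* In a straight channel the transverse Coriolis force is absorbed
  entirely by the pressure field (in 2D its curl vanishes for
  divergence-free flow), so the fully developed throughflow profile
  cannot skew. The familiar trailing-wall deflection appears wherever
  streamlines curve; the rotating-channel verification therefore
  measures the jet deflection downstream of an expansion — the planar
  lab-on-a-disc "Coriolis switch" configuration — with the
  high-Rossby phase (water) as the working fluid, and checks that the
  deflection is toward the trailing wall and antisymmetric in the
  rotation sense. The mesh-sensitivity pair (20 vs 10 µm) compares
  mid-channel throughflow profiles, the quantity the original mesh
  study compared.
* A thin wall film of the low-viscosity dispersed phase has no contact
  line within the plane (its contact lines are on the top and bottom
  walls, which the plane does not represent), so planar wall films are
  far more persistent than physical ones. At the device's T-junctions
  this is decisive: across the capillary-number and flow-ratio ranges
  we explored, the emerging water tongue always found a low-resistance
  wall-film path (the 64:1 viscosity contrast makes any connected water
  filament an efficient bypass) and the junction settled into stable
  co-flow instead of pinching. Periodic droplet generation in the plane
  therefore uses the rotating **flow-focusing** configuration (the
  validation geometry), where the dispersed thread is sheared at the
  channel axis away from the walls and pinch-off is robust. The
  Bond-number trend study (`emulsification_trend()`) runs that
  geometry at three rotation frequencies inside the dripping window,
  with feed velocities scaling as $\Omega^2$ (centrifugal pumping):
  droplet area falls and generation rate rises monotonically with
  $Bo$, the direction the source study reports for both of its
  systems. Droplet populations from the planar *device* T-junction are
  correspondingly **not** available at desk scale; the quantitative
  device-population goals (mean $\tilde D$, CV) remain open in this
  planar implementation and are stated as such rather than
  approximated by a different geometry. For the same reason the
  contact-line dynamics are approximate: a seeded hydrophobic droplet
  retracts toward — but pins a little short of — its equilibrium cap
  (effective angle within roughly 10–13 degrees of the prescribed
  112°), while wetting caps converge closely.

## Problem sizes

The shipped tests and the verification suite use deliberately small
configurations: the static droplet at $R/\Delta x = 20$ (a 200 µm box),
advection benchmarks at 64², single-phase rotating flows at 20 and
10 µm on millimetre-scale toys, truncated two-phase junction runs
(shortened flow-focusing channel, single-junction device) at 25–40 µm
cells for 40–75 ms of physical time. These sizes were
chosen so the whole verification battery completes on one desktop core
while still resolving every channel by at least 6–10 cells.

## Known limitations

* Planar-2D only; full-3D operators are not provided. All quantitative
  comparisons against published 3D droplet populations are labelled
  scaled-down and carry relaxed tolerances.
* Static contact angle prescription only; no dynamic contact-angle or
  contact-line microphysics. Wall-relaxation toward equilibrium caps is
  correspondingly slow and approximate.
* The constant-coefficient projection assumes near-matched densities
  (ratio ≲ 1.3); it is exact for the study's fluid pairs' regime but
  not a general variable-density scheme.
* Merging is reported, not suppressed: whether a recorded merge is
  physical or a resolution artifact is left to the analyst, as in the
  source study's own comparison with experiment.
* The dripping/jetting classifier uses literature-scale thresholds
  ($Ca^* = 0.1$, $We^* = 1$); the study gives only "small"/"large".
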