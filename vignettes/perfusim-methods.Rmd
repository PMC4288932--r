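---
title: "Modelling perfusion shear and cellular growth in voxelized scaffolds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling perfusion shear and cellular growth in voxelized scaffolds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

perfusim simulates the perfusion of culture medium through porous,
additive-manufactured (AM) titanium scaffolds and the resulting
shear-stress-regulated growth of bone precursor cells ("cellular growth":
migration, attachment and proliferation, lumped into one volumetric
deposition process). This vignette is the package's account of the model,
its numerical treatment and the design decisions behind it.

## The fraction-field model

All state lives on a uniform voxel grid. A single scalar per voxel, the
fluid fraction $f \in [0, 1]$, encodes geometry and growth at once:
$f = 1$ is open pore, $f = 0$ is solid strut (titanium or dense matrix),
and intermediate values represent a partially grown cellular layer on a
surface. This single-field representation is what lets growth feed back
into the flow without remeshing: depositing matrix simply lowers $f$.

### Flow

The medium is treated as incompressible and Newtonian, and the flow as
laminar; at the micrometre scales and sub-mm/s velocities involved the
Reynolds number is far below 1 (the solver reports it and warns above
10). The momentum equation is solved with a fractional-step (projection)
scheme on a staggered marker-and-cell grid:

1. an explicit momentum step forms the intermediate velocity
   $u^* = f\,(u + \Delta t\, F(u))$, where $F$ collects first-order
   upwind convection and central-difference diffusion;
2. a pressure Poisson equation
   $\nabla \cdot (f \nabla P) = (\rho / \Delta t)\, \nabla \cdot (f u^*)$
   is solved by Jacobi-preconditioned conjugate gradients, with Neumann
   conditions on walls, solid material and the prescribed-flux inlet, and
   a Dirichlet reference pressure on the outlet face;
3. the velocity is corrected as
   $u = f\,(u^* - (\Delta t/\rho) \nabla P)$.

Multiplying both the intermediate velocity and the correction by the
liquid fraction is the momentum sink that enforces $u \equiv 0$ in solid
material and damps the partially grown cells at the surface; no body-fitted
meshing or immersed-boundary machinery is needed, which is what makes
the transient growth coupling cheap. Steady state is declared when the
maximum relative velocity change per pseudo-step falls below `tol`
(default $10^{-6}$).

Boundary conditions mirror a perfusion bioreactor: a flat velocity
profile on the inlet face, a reference pressure on the outlet face,
free-slip no-penetration on the lateral boundaries ("zero flux" reads as
a statement about flux, not velocity, so the tangential velocity is left
stress-free), and all-fluid buffer slabs up- and downstream so the inlet
and outlet conditions do not distort the flow inside the scaffold.

Numerical choices worth knowing about:

* **Staggered rather than collocated unknowns.** Cell-centred velocities
  with an explicit projection are checkerboard-unstable; face-normal
  velocities avoid that. Shear and summaries are reported at cell
  centres by linear interpolation.
* **Wall treatment.** Where a velocity node sits in fully solid material
  the diffusion stencil uses a mirror ghost, i.e. no-slip imposed at the
  intervening cell face — the discrete bone-fluid interface — rather
  than at the solid node centre. This keeps plane-channel flows
  second-order accurate (the discrete parabola is reproduced to solver
  tolerance). The mirror terms are folded into the update implicitly,
  which is unconditionally stable for that part of the operator and
  leaves the steady state unchanged.
* **Pseudo-time step.** $\Delta t = 0.9 / (6\nu/h^2 + 2\sum_i |u_i|_{max}/h)$,
  the combined explicit advective-diffusive bound with a 0.9 safety
  factor (the factor 2 on the advective term covers the mirrored
  convection stencil at walls). Only the steady state is of interest, so
  the largest stable step is the right choice.
* **Inner pressure tolerance.** During the pseudo-time march the Poisson
  solve runs at a loose relative residual ($10^{-3}$); the error this
  leaves in the momentum balance is $O(\Delta t)$-small and does not move
  the fixed point appreciably. A final projection at the tight tolerance
  ($10^{-8}$) makes the returned field divergence-free to full accuracy;
  mass conservation checks run on that final state.
* **Connectivity.** Before solving, fluid cells are labelled by
  connected components; a solve on a domain with no open inlet-outlet
  path aborts with a blocked-domain error (the coupled simulation
  catches it and flags the occlusion time). Isolated fluid pockets are
  pinned to the reference pressure and carry no flow.
* **Upwind convection.** First-order upwinding is diffusive, but at cell
  Reynolds numbers of order $10^{-3}$ convection is negligible and
  robustness wins.

### Shear

The mechanical stimulus is the local shear-stress magnitude at the
growth interface. The package computes the three off-diagonal stress
components from centre-interpolated velocities,
$\tau_x = \mu(\partial u/\partial y + \partial v/\partial x)$ and
cyclically, and reports
$\tau = \sqrt{\tau_x^2 + \tau_y^2 + \tau_z^2}$. Gradients are central
differences; toward a fully solid neighbour a one-sided half-cell
difference to the no-slip face is used, so the shear is sampled on the
fluid side of the interface. On a resolved plane channel the
wall-adjacent value reproduces $6 \mu \bar{u} / h$ to a few percent.

### Growth

Growth sites are voxels with some fluid ($f > 0$) adjacent to fully
solid material ($f = 0$ in a face neighbour — strut or completely
filled matrix); once a voxel fills completely the front advances to its
fluid neighbours. Recruiting neighbours on *any* partial fill may look
more permissive, but it makes the front advance one voxel per macro-step
however small the step, so the deposited volume would depend on the
coupling step with no convergent limit; advancing on complete fill is
deposition-limited and macro-step-invariant. The deposition law is
linear in shear,

$$\Delta G = \min(A\,\tau,\; r_{max})\,\Delta t,$$

active only inside the window $\tau_{min} \le \tau \le \tau_{max}$:
below it the stimulus is insufficient, above it cells are washed off the
surface (the upper cutoff can be disabled to quantify its effect — it
zeroes deposition but never erodes existing matrix). $\Delta G$ is
subtracted from $f$ and clamped at zero; excess deposition in a nearly
full voxel is discarded rather than redistributed, since no spill-over
rule is physically established. Growth is disabled inside the buffer
slabs, which are defined to stay fully liquid.

Default parameters (all changeable through `growth_parameters()`):

| parameter | default | unit | meaning |
|---|---|---|---|
| $A$ | $1.5\times10^{-4}$ | 1/(Pa s) | growth factor |
| $\tau_{min}$ | $5\times10^{-5}$ | Pa | critical stimulatory shear (0.05 mPa) |
| $\tau_{max}$ | $5.6\times10^{-2}$ | Pa | wash-out shear (56 mPa) |
| $r_{max}$ | $1.5\times10^{-5}$ | 1/s | cap on the volumetric rate |
| macro_dt | 3600 | s | growth step between flow re-solves |

A note on units: the growth factor is tabulated in the source literature
without units next to a maximum growth rate in $s^{-1}$; the two are
dimensionally consistent only if $\tau$ enters in Pa and $A$ in
Pa$^{-1}$s$^{-1}$ ($A \tau_{max} \approx 8.4\times10^{-6}\,s^{-1}$, just
below the cap). That convention is adopted here, with the explicit rate
cap as a guard.

### Quasi-steady coupling

The flow relaxes in milliseconds; growth acts over hours. The coupled
driver therefore alternates: solve the flow to steady state on the
current $f$ (warm-started from the previous solution), evaluate shear,
apply one growth macro-step, repeat. The flow is re-solved after every
macro-step. Halving the macro-step changes the final growth fraction by
well under 2% on the test scaffolds (this invariance is asserted in the
test suite), because the deposition rate is capped and the flow responds
smoothly to the small per-step geometry change.

## Scaffold generation

The geometry generator emulates the unit-cell design route of AM
implants:

1. **Lattice.** A block of cubic unit cells (600 µm side by default) is
   filled with regular octahedra whose six vertices sit at the face
   centres of each cell — the standard octahedral cell that tessellates
   in 3D. Shared vertices are stored once; struts are vertex-index
   pairs. (The published design route does not state vertex positions;
   face centres are the natural reading that reproduces the connectivity
   and tessellation.)
2. **Randomization.** For the "30% randomized" design, every vertex
   coordinate is displaced independently per axis by a uniform draw in
   ±30% of the cell side, keeping the edge list — and hence strut
   connectivity — fixed. A bounded uniform draw is the minimal reading
   of "±30%". Vertices on the outer envelope move only tangentially so
   the inlet/outlet cross-sections stay well defined. The perturbation
   is driven by a single seed and is bit-reproducible.
3. **Slicing.** Struts are cut by horizontal planes every 50 µm (the SLM
   layer height) to locate laser melt points; strut endpoints are kept,
   and any residual gap longer than one layer interval in 3D (in-plane
   struts, or nearly horizontal struts of randomized lattices) is
   subdivided to the same spacing — otherwise those struts would
   voxelize as disconnected beads, which the physical melting process
   never produces.
4. **Voxelization.** A spherical kernel is swept over the melt points:
   voxels whose centre lies within the kernel radius of any point become
   solid ($f = 0$), the rest fluid ($f = 1$). The assignment is binary;
   partial fractions arise only later, from growth.
5. **Porosity calibration.** The published designs are specified by
   porosity (67.5% regular, 69.2% randomized), not strut radius, so the
   kernel radius is bisected until the voxelized porosity hits the
   target; porosity is monotone in the radius, making the calibration
   deterministic.

What the generator does **not** emulate: melt-pool physics and surface
roughness of the real SLM process, strut-diameter variability,
micro-porosity inside struts, and any deviation of the CAD design from
the manufactured part. Passing tests on generated scaffolds therefore
validates the transport-and-growth model on idealized geometry, not the
fidelity of any printed implant.

## Problem sizes and tolerances used in the shipped analyses

The validation suite runs on analytic fixtures (plane channels of 10-40
voxels across, a tube of radius 8 voxels) and small scaffolds of $2^3$
unit cells. The acceptance analysis (`scripts/acceptance.R`) uses $3^3$
unit cells at the native 36 µm grid (50³ scaffold voxels plus 8-voxel
buffers), steady-flow tolerance $10^{-6}$ ($10^{-5}$ within the coupled
loop), and growth macro-steps of 20000 s chosen so the reporting times
16.7/50/83.3/120 h land exactly on step boundaries. Five randomization
seeds are averaged for the randomized-vs-regular pressure comparison.
These sizes resolve the unit-cell architecture (pores of 5-8 voxels
across) while keeping each coupled 120 h simulation cheap enough to
re-run routinely.

## Known limitations

* The native 36 µm grid resolves a 600 µm unit cell with ~17 voxels;
  strut surfaces are staircased, and wall shear on oblique surfaces
  carries first-order geometric error. The Poiseuille and
  Hagen-Poiseuille oracles bound this error on aligned and curved
  geometry respectively.
* Growth is volumetric deposition with no transport of nutrients or
  oxygen, no cell seeding dynamics, and no mechanics of the deposited
  matrix; the law is deliberately the simplest shear-linear form.
* The window thresholds and growth factor come from the perfusion
  literature and carry substantial uncertainty; conclusions should rest
  on comparisons (between designs, velocities, or constraint settings)
  rather than absolute growth percentages.
* The momentum sink treats a partially filled voxel as a uniform
  porous plug (no sub-grid wall position); with a one-voxel growth film
  this is the modelling resolution limit, not a numerical bug.
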