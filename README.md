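# perfusim

Microscale simulation of perfusion flow and shear-regulated cellular
growth inside additive-manufactured (AM) porous scaffolds.

Porous titanium implants are designed to let body fluid or culture
medium perfuse through them; the wall shear stress this flow exerts on
strut surfaces regulates how bone precursor cells migrate, attach and
proliferate ("cellular growth"). perfusim couples the two processes on a
shared voxel grid so that growth reshapes the pore space and the flow —
and hence the stimulus — responds:

* **Geometry.** Octahedral unit-cell lattices (600 µm cells by default),
  optionally with reproducible ±30% vertex randomization, are sliced
  into laser melt points at 50 µm layers and voxelized with a spherical
  kernel, emulating the selective-laser-melting build; the kernel radius
  is calibrated to a target porosity.
* **Flow.** Steady incompressible Navier–Stokes by a projection
  (fractional-step) method on a staggered voxel grid. A per-voxel fluid
  fraction *f* ∈ [0, 1] (1 = pore, 0 = strut, between = growing cell
  layer) multiplies both the intermediate velocity and the pressure
  correction — a momentum sink that enforces no-slip in solid material
  and lets growth alter the flow without remeshing:

  u\* = *f* (u + Δt·F(u)),  ∇·(*f*∇P) = (ρ/Δt) ∇·(*f* u\*),  u = *f* (u\* − (Δt/ρ)∇P)

* **Growth.** A linear, shear-windowed law on interface voxels:
  ΔG = min(A·τ, r_max)·Δt, active for τ_min ≤ τ ≤ τ_max
  (defaults A = 1.5×10⁻⁴ (Pa·s)⁻¹, window 0.05–56 mPa,
  r_max = 1.5×10⁻⁵ s⁻¹), where τ is the local shear-stress magnitude
  τ = (τ_x² + τ_y² + τ_z²)^½ from the off-diagonal stress components.
* **Statistics.** Fluid-volume-normalized log-binned shear histograms
  (mean, mode, sd, skew, excess kurtosis), growth volume fraction over
  time, overall growth rate, pressure drop, velocity extrema and Darcy
  permeability k = µLQ/(A·ΔP).

The package is aimed at computational tissue engineers exploring how
strut architecture and perfusion rate shape the mechanical
micro-environment — e.g. regular vs. randomized lattices, or the effect
of the wash-out shear cutoff — before committing to prints or culture
experiments.

## Worked example

Build a 2×2×2-cell regular scaffold calibrated to 67.5% porosity, solve
the steady flow at an inflow of 0.02 mm/s, and grow for 24 h:

```r
library(perfusim)

lat <- build_regular_lattice(c(2, 2, 2), unit_cell_size = 600)
radius <- calibrate_kernel_radius(lat, target_porosity = 0.675, voxel_size = 36)
scaffold <- attr(radius, "field")

bc <- flow_bc(inflow_velocity = 2e-5, flow_axis = "z",
              buffer_upstream = 8, buffer_downstream = 8)
domain <- assemble_domain(scaffold, bc)
state <- solve_steady_flow(domain, bc, fluid_properties())
flow_summary(state, domain)
#> flow_summary: max axial velocity 0.000177 m/s, mean speed 3.12e-05 m/s,
#>   max pressure variation 0.0157 Pa, permeability 1.32e-09 m^2

shear <- compute_shear_field(state, domain)
shear_histogram(shear, domain)
#> shear_statistics: n = 5952, mean 0.00039 Pa, mode 0.000365 Pa,
#>   sd 0.000622, skew 3.57, kurtosis 12.51

params <- growth_parameters(enforce_max_constraint = FALSE, macro_dt = 7200)
history <- run_coupled_simulation(domain, bc, fluid_properties(), params,
                                  total_time = 24 * 3600)
history
#> growth_history: 13 time points over 24.0 h, final growth 0.122%
```

Reading the numbers: the flow accelerates about 9× from the inlet value
inside the narrowest channels (max axial velocity 0.177 mm/s), the
pressure drop across this small block is ~16 mPa, and the permeability
(~1.3×10⁻⁹ m²) is in the range typical of open-porosity AM lattices.
Interface shear averages ~0.4 mPa at this perfusion rate — above the
0.05 mPa stimulation threshold almost everywhere, far below the 56 mPa
wash-out limit — and the scaffold accrues 0.12% of its pore volume as
new matrix in the first day. Raising the inflow tenfold scales shear
almost linearly (creeping flow) and accelerates growth accordingly.

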