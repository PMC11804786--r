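# coralflow

Seawater flows not only around a branching coral but *through* it. The
skeleton of an *Acropora*-type branch is a porous aragonite cylinder whose
pore space is organized — a central axial channel with bending points,
annular corallite cavities ringing it, radial mouths under surface bumps, a
wide apical corallite at the tip — and an ambient current sets up pressure
differences that drive a slow internal flow through that system. `coralflow`
is an R package for scientists studying this internal hydrodynamics and its
consequence under ocean acidification: the same internal flow that feeds
polyps can carry protons into the skeleton and dissolve it from the inside.

The package provides, end to end:

* **Synthetic coral geometry** — labelled voxel volumes
  (solid / inner pore / external pore) emulating segmented micro-CT stacks,
  with exact-integer porosity accounting, reachability-based inner-pore
  labelling, pore filling, rotation and majority-vote downsampling.
* **A D3Q19 BGK lattice-Boltzmann solver** (compiled core) with the
  seabed-channel boundary set: inlet open-channel velocity profile,
  constant-pressure outlet, periodic transverse sides, free-slip sea
  surface, half-way bounce-back on the seabed and skeleton, explicit
  lattice/physical unit conversion, and quasi-steady detection from the
  domain kinetic energy.
* **Flow statistics** — vorticity/enstrophy fields, tracer seeding, RK4
  streamline tracing, residence-time distributions with 95%-retention
  trimming, volume flux, upstream/downstream asymmetry tables, and the
  axial-channel decomposition of vertical vs transverse flow.
* **An acidification dissolution model** — the equivalent carbonate-tube
  advection-reaction problem with the exponential aragonite rate law
  `-r = 2.5e-7 (exp(1.98e5 C[H+]) - 1)` (mol m^-3 s^-1,
  `C[H+] = 10^(3-pH)`), its method-of-characteristics closed form, an
  independent upwind solver, two acid-supply scenarios, inner-radius and
  porosity-change evolution, and the flexural-rigidity reduction
  `G = (V0^1.358 - Vt^1.358)/V0^1.358 x 100%` via the area-volume allometry
  of branching skeletons.
* **A reproducible pipeline** — `run_pipeline()` chains
  generate / simulate / analyze / dissolve from one (YAML) configuration
  and seed, writing TIFF+JSON geometry, VTK fields, CSV statistics and a
  checksummed JSON manifest; `inst/cli/coralflow` is a thin command-line
  front end.

## Worked example

```r
library(coralflow)

# a coral-like voxel volume at the default study conditions
geom <- generate_coral(coral_params())
geom
#> <voxel_geometry> 64 x 64 x 128 voxels, spacing 0.000375 m
#>   solid: 52246  inner pore: 30227  external pore: 441815
#>   provenance: synthetic coral (seed 1)

# ambient current at Re ~ 10 (0.9 mm/s over a 1.2 cm branch)
reynolds(0.0009, 0.012)
#> [1] 10.8
cfg <- flow_config(u_inlet = 8.33e-4, width = 0.012, spacing = geom$spacing,
                   tau = 0.9)
field <- run_to_quasi_steady(geom, cfg)        # ~4 minutes, 1 CPU

# upstream/downstream asymmetry over the inner pore space
reg <- coral_regions(geom)
asymmetry_differences(field, reg$slice_pairs, mask = geom$labels == 1L)
# all nine upstream-minus-downstream differences (pressure, velocity,
# enstrophy x top/center/bottom) are positive: upstream dominance

# dissolution projection for the equivalent carbonate tube of this branch
p <- attr(geom, "params")
pipe <- pipe_model(R_O = p$radius * geom$spacing,
                   R_I = p$channel_radius * geom$spacing,
                   H = p$height * geom$spacing, n0 = 0.367)
project_scenario(pipe, list(
  acid_scenario("inside-acid", pH = 8.10, t_years = 1, label = "2023"),
  acid_scenario("inside-acid", pH = 7.87, t_years = 1, label = "2100")))
#>   label   pH      rate N_percent G_percent
#> 1  2023 8.10 9.550e-07   0.01904   0.01011
#> 2  2100 7.87 3.363e-06   0.06710   0.03566
```

The projection reads: dropping open-ocean pH from 8.10 to 7.87 multiplies
the aragonite dissolution rate by ~3.5; at the 2100 rate this equivalent
tube loses 0.067% of its porosity-normalized skeleton volume and 0.036% of
its flexural rigidity per year. (Full-resolution studies with measured pore
fluxes and additional local acid sources report far larger damage; the
synthetic desk-scale branch is deliberately conservative.)

`autoplot()` works on residence statistics, asymmetry reports and
dissolution projections; `plot_convergence(field)` shows the kinetic-energy
trace behind the quasi-steady decision.

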