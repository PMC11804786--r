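---
title: "Methods: skeletal flow simulation and acidification projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: skeletal flow simulation and acidification projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`coralflow` models the passive water flow inside the porous skeleton of a
branching coral and the long-term dissolution of that skeleton under ocean
acidification. This vignette is the package's own account of the science: the
models, their assumptions, the tunable parameters, and the numerical choices
that were genuinely open.

## The physical picture

A branching coral skeleton is a vertical porous aragonite (CaCO~3~) cylinder
standing on the seabed. Its pore space is organized: a central axial channel
runs up the branch (with slight bends at a few inflection points), annular
corallite cavities ring the channel at intervals and open to the surface
through radial mouths, each mouth sitting under a surface bump, and the tip
carries a wider apical corallite. When an ambient current passes the branch,
pressure differences between the upstream and downstream faces drive a slow
internal flow through this connected pore system. That internal flow matters
twice over: it transports dissolved material (helping polyp growth), and —
under acidified conditions — it carries protons into the skeleton's interior
where they dissolve aragonite from the inside.

## Synthetic geometry

Micro-CT segmentation of real skeletons is out of scope; the package instead
generates labelled voxel volumes with the same five structural features
(surface bumps, annular interconnected radial corallites, bending axial
channel, apical corallite, optional through-wall defect). All primitives are
rasterized by centre-of-voxel inclusion, so every count used in porosity
formulas is an exact integer. The canonical label scheme is
`0 = solid, 1 = inner pore, 2 = external pore`; raw two-label stacks
(`1 = solid, 2 = pore`) are accepted and relabelled.

"Inner" pore space is defined by reachability: a pore voxel is external if a
face-connected (6-connectivity) pore path links it to the domain boundary.
6-connectivity is the conservative choice for fluid percolation on voxel
grids — diagonal contacts do not let water through. Because a real corallite
mouth is open, strict reachability would classify the entire channel system
as external; the generator therefore records its openings, and
`label_inner_pores(cap_openings = TRUE)` seals them during the flood fill
(the apical mouth with a cylindrical plug, radial mouths with balls at the
surface). Relabelling is idempotent. A `seal_openings` generator flag builds
strictly sealed interiors for testing the reachability definition itself.

Two porosity conventions coexist deliberately. The printed micro-CT
bookkeeping divides pore count by *solid* count (and can exceed 1); the
conventional porosity divides by total volume. `porosity()` exposes both
(`"specific"`/`"whole"` vs `"fraction"`); the dissolution model's initial
porosity `n0` uses the conventional fraction by default, since a fraction in
(0, 1] is what a porosity-change *ratio* should be normalized by.

### Default study conditions

The default `coral_params()` set was chosen once, from the reported
dimensions of a real branch (about 4 cm tall, 1.2 cm wide) and a desk-scale
resolution policy, and defines the conditions every downstream statistic is
computed under:

| parameter | default | rationale |
|---|---|---|
| grid | 64 x 64 x 128 voxels | largest grid a laptop-scale run resolves in minutes |
| spacing | 3.75e-4 m | makes the 32-voxel branch diameter 1.2 cm |
| branch radius / height | 16 / 96 voxels | aspect ratio of the real branch |
| channel radius | 4 voxels (1.5 mm) | resolvable axial canal |
| bends | 3, amplitude 2.5 voxels | the reported number of inflection points |
| corallite rings | 8, half-thickness 2 | annular cavities joined to the channel |
| mouths per ring | 3, radius 2 | open azimuths, golden-angle placement |
| bump amplitude | 2 voxels | surface roughness co-located with mouths |
| apical funnel | radius 5 voxels | wider tip corallite |

The generator is a pure function of its parameter list including the seed.

## Lattice-Boltzmann flow solver

The solver is a D3Q19 single-relaxation-time (BGK) scheme: 19 discrete
populations per cell relax toward the second-order low-Mach equilibrium with
rate 1/tau and then propagate along the lattice directions. Macroscopic
fields are moments: density is the population sum, momentum the first moment,
and pressure follows the ideal lattice equation of state `p = C^2 rho / 3`
with `C = dl/dt`. The BGK viscosity is `nu = C^2 dt (tau - 1/2) / 3`.

Boundary conditions reproduce a submerged branch on the seabed:

* **inlet** (x = 0): prescribed velocity profile at unit density. The open
  channel profile shape is not standardized; the default is the
  half-Poiseuille `u(z) = u_max (2*zeta - zeta^2)` (zero at the bed, maximum
  and zero shear at the surface), consistent with the bed/surface pair below.
  A 1/7-power profile is selectable.
* **outlet** (x = nx-1): fixed density with zero-gradient velocity — a
  simple constant-pressure condition that is stable at low Re. Its error is
  local (a few cells); statistics are taken away from the outlet.
* **transverse sides**: periodic.
* **sea surface** (top): free-slip by specular reflection.
* **seabed and skeleton**: half-way bounce-back, placing the no-slip wall
  half a cell outside the last fluid layer. Bounce-back is local and robust
  on arbitrary voxel geometry, which is why it is the standard choice for
  porous-media LBM.

Discretization is derived, not chosen by hand: given the physical viscosity
(1.0e-6 m^2/s for seawater), the voxel spacing and a target tau, the time
step follows from the viscosity relation and the lattice inlet velocity from
the time step. If the implied lattice velocity exceeds a tenth of the lattice
speed (the low-Mach contract), tau is reduced toward 0.55 to restore it;
combinations that would need tau below 0.55 are rejected — the BGK accuracy
window 0.55 <= tau <= 1.2 is enforced rather than warned about. The state is
initialised at rest equilibrium and the inlet ramps up over a configurable
number of steps to avoid an initialization pressure shock.

A run is declared quasi-steady when the relative change of domain-total
kinetic energy across consecutive check windows (default every 100 steps)
stays below tolerance for three windows in a row, after the ramp. The
kinetic-energy trace and optional monitor-point traces are returned with the
field so convergence can be inspected (`plot_convergence()`).

Verification anchors, all in the test suite and the acceptance script:
exact mass conservation in periodic solid-free domains; shear-wave decay
reproducing nu(tau) within 1% on a 32^3 grid; the body-force-driven
bed/surface channel matching the analytic half-parabola to better than 0.5%
at 64 transverse cells (the measured error is ~1e-5 once the slowest
diffusive mode, time constant ~H^2/(pi/2)^2/nu steps, has decayed); an
obstacle-free inlet/outlet domain carrying the inlet profile through the
interior within 1%.

### Desk-scale policy

Default grids stay at or below 96 x 96 x 192 and Re <= 150. The reference
configuration used throughout — the default coral at Re = 10 (inlet 0.833
mm/s, tau = 0.9, lattice velocity 0.042) — reaches the quasi-steady plateau
in roughly 1700 steps, about four minutes on one CPU. Coarse-grid BGK at the
turbulent regimes of full-resolution studies (Re >= 354) is unstable and
outside the supported envelope; `validate_config()` flags such requests.

## Flow statistics

**Vorticity and enstrophy.** Central differences in the interior, one-sided
at domain boundaries; enstrophy is `|curl u|^2 / 2`. Velocity is zero on
solid voxels, so near-wall stencils see the no-slip wall; solid cells are
masked out of statistics.

**Streamlines and residence time.** Tracers are seeded uniformly in a sphere
about the pore-space centroid of the analysed region (resampling off solid),
then integrated with fixed-step RK4 in *arc length* (step 0.25 voxel) through
trilinearly interpolated velocity, terminating on leaving the domain,
stagnating, or a step cap. Residence time in a region sums segment length
over speed-at-segment-start for segments whose midpoint lies inside — the
printed formula's reading of "Delta l / Delta u". The summary retains
streamlines up to the 95th-percentile residence time before averaging
(trimming never-exiting paths), reports the untrimmed mean alongside, and
normalizes the histogram to total frequency 1. The average volume flux is
inner-pore volume over mean residence time.

The independent cross-check is a deliberately different integrator:
fixed-time-step forward Euler advection (`advect_particles()`). The
comparison is made on matched particle sets: only transiting particles
(whose streamline leaves the domain) enter it, since trapped or
recirculating paths have no finite residence time and each integrator merely
reports its own cap there, and the 95% trim selects the *same* particles for
both estimators — trimming each estimator's sample separately would compare
different subsets. On the reference coral field the two integrators agree on
this matched trimmed mean within 5%; on uniform flow both are exact.

**Asymmetry report.** For paired upstream/downstream slabs the report gives
means of pressure, velocity magnitude and enstrophy over inner-pore voxels,
their difference (upstream minus downstream) and standard errors. The slab
extents are analysis configuration; the defaults cover the top, centre and
bottom *thirds* of the corallite span, so each mean aggregates the full
annular cavity system of its section. Thin single-ring slices are offered by
the same machinery but are dominated by where individual mouths sit — an
artefact of the synthetic geometry's three discrete mouths per ring, not a
flow property. At the reference conditions all nine differences are positive
(upstream dominance), the counterpart of the full-resolution observation.

**Axial decomposition.** Per channel section (TipTop/Top/Center/Bottom,
fractions 0.85/0.6/0.3 of the corallite span), the mean speed and the mean
signed ratio u_z/|u| over channel pore voxels, excluding cells below a speed
floor whose direction is noise. At the reference conditions the vertical
fraction is markedly higher in the Top section than the Bottom — upward flow
dominates the upper channel while the channel base is fed transversely.

**Monitor points.** The interior monitor is placed by a deterministic
shelter rule: mid-annulus of the corallite ring nearest a quarter height, at
the azimuth farthest from that ring's mouths; the ambient reference sits
upstream of the branch at 5/8 height. At the reference conditions the
interior speed is a factor of roughly 300 below free stream. The synthetic
skeleton is more open than a real one (its pores are millimetre-scale), so
this attenuation is weaker than the per-mille ratios of full-resolution CT
studies; the package asserts only the order-of-magnitude separation
(>= 100x).

## Acidification dissolution model

The branch is reduced to an equivalent homogeneous aragonite tube (outer
radius R_O, inner radius R_I, length H, mineral density 2700 kg/m^3, molar
mass 0.100 kg/mol). Proton transport along the tube is advection-reaction
(diffusion neglected as the weaker process):

* the rate law is the exponential fit
  `-r = 2.5e-7 (exp(1.98e5 C) - 1)` mol m^-3 s^-1 taken as given; its two
  coefficients are the only empirical constants. The decay constant of the
  closed-form profile is *derived* from them (2.5e-7 x 1.98e5 = 0.0495 s^-1)
  rather than re-entered, removing a 1-in-500 rounding inconsistency between
  printed constants. The fit is valid near seawater pH; evaluating it below
  pH ~ 5.5 overflows and raises a domain error.
* the method-of-characteristics steady solution gives C(x) in closed form;
  it recovers C(0) = C0 exactly and decays monotonically.
* the independent numerical route is first-order upwind. Its steady state is
  solved directly by a per-cell Newton march in x (the exact fixed point of
  the time-marched scheme), with an explicit time-marching mode retained for
  transient questions and the pure-advection limit. At 1e4 cells the two
  routes agree to ~0.3% of the inlet concentration — *beyond the reaction
  entrance layer*. At pH 6 the closed form falls from C0 to below 1% of C0
  within a boundary layer far thinner than any uniform grid cell, so the
  first few cells cannot match pointwise at any practical resolution; the
  comparison therefore excludes the first 1% of cells and says so here.

Two scenarios bracket where the acid comes from. Scenario 1 (outside acid):
protons produced outside are advected in and consumed essentially at the
entrance, so the tube-averaged rate is the supply rate
`r = (Q / (H pi R_I^2)) 10^(3-pH)`; the implementation verifies the
complete-consumption assumption against the analytic profile (C(H)/C(0) <
1e-3) and falls back to the exact in/out difference with a warning if flow is
too fast. Scenario 2 (inside acid): a sustained low-pH microenvironment
dissolves at the constant rate-law value.

Dissolution widens the inner radius exponentially,
`R_I(t) = R_I(0) exp(r M t / 2 rho)`; the growth exponent stays of order
1e-2 per century at projected rates, so the linearized form is also provided
and the gap is bounded by the exponent squared. The porosity change ratio N
follows the printed closed form and is algebraically identical to the
skeleton-volume difference route (verified to machine precision). The
flexural rigidity reduction uses EI proportional to area squared and the
measured area-volume allometry of branching skeletons (slope 1.4728, taken
as given), i.e. G = (V0^e - Vt^e)/V0^e x 100% with e = 2/1.4728 = 1.358,
where V is the *remaining solid* tube volume — stated explicitly because the
area symbols could be misread as pore areas. Years convert to seconds with
the Julian year (3.15576e7 s). The 2023 baseline ambient pH is a parameter
(default 8.10); projections use the 2100 open-ocean estimate pH 7.87.

## What the synthetic tests do and do not show

The synthetic generator emulates the topology and proportions of a real
branching skeleton, not its microstructure: real pore walls are rough and
micro-porous, pore sizes reach down to tens of microns, and corallite
placement is irregular. Quantities that depend only on topology and the
governing equations (mass conservation, viscosity recovery, channel physics,
the dissolution identities, the oracle agreements) transfer directly.
Quantities printed by full-resolution CT studies — per-mille interior
velocity ratios, residence-time curves at Re up to 500, the specific
porosity-increase and rigidity-loss percentages driven by supplementary flux
tables — are *not* reproduced at desk scale; for those the package asserts
the qualitative structure only (signs, orderings, order-of-magnitude
separations) and reports its own computed values.

## Numerical choices and degenerate inputs

* Ties in block-majority downsampling resolve to solid, preserving thin
  walls; an inner/external pore tie resolves to inner.
* Porosity with no solid voxels in the region is an explicit error (zero
  denominator), not NaN.
* Streamline stagnation threshold defaults to 1e-6 of the field's maximum
  speed; a zero-velocity start terminates immediately as stagnation.
* The outlet's equilibrium construction loses accuracy within a few cells
  of the boundary; inlet-consistency checks compare at mid-domain.
* Tests and the acceptance script use scaled problem sizes (64 x 64 x 128
  reference grid, 250 tracers, 1e4 transport cells), chosen as the package's
  desk-scale study conditions.

## Interfaces

Geometry volumes travel as multi-page TIFF stacks with a JSON metadata
sidecar; flow fields as legacy ASCII VTK structured points (ParaView-ready);
statistics and traces as CSV; run manifests as JSON with MD5 checksums. The
pipeline (`run_pipeline()`, or the `inst/cli/coralflow` script) chains
generate, simulate, analyze and dissolve stages with a single global seed
fanned out to fixed per-stage sub-seeds, and re-running a configuration
reproduces deterministic outputs bit-identically.

Tabular results (residence statistics, asymmetry reports, axial profiles,
dissolution projections, validation findings) are tibbles with `autoplot()`
methods; run objects have `glance()` summaries. The voxel and field
containers themselves are plain arrays inside lightweight S3 objects — the
natural shape for 3-D grids.
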