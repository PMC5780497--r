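# flipdg

Simulation and calibration of **fluorescence loss in photobleaching (FLIP)**
experiments on single cells, built around a reaction–diffusion model with a
semipermeable nuclear membrane, discretized by a symmetric interior-penalty
discontinuous Galerkin (IPDG) method.

## The problem

In a FLIP experiment a small region of the cytoplasm is bleached repeatedly
by a high-intensity laser while the whole cell is imaged between pulses.
Because molecules are transported toward the bleach spot, fluorescence falls
everywhere — and *how fast* it falls at each position encodes the transport
physics: the diffusion coefficient of the tagged protein, the strength of
local hindrance (binding to or partitioning into subcellular structures),
and the permeability of the nuclear membrane. `flipdg` turns a FLIP image
stack into estimates of all of these at once.

## The model

The observed intensity is split into a freely diffusing pool u and a
locally hindered pool u_b (c = u + u_b), coupled by first-order mass-action
exchange with a spatially resolved binding rate:

    u_t     = div(alpha grad u) + k⁻ u_b − k⁺(x) u − chi_B theta(t) beta u
    (u_b)_t =                     k⁺(x) u − k⁻ u_b − chi_B theta(t) beta u_b

* `alpha` — diffusion coefficient of the free pool (um²/s); the hindered
  pool does not diffuse.
* `beta` — effective bleach rate (1/s), active only inside the bleach disk
  (chi_B) while the laser is on (theta).
* `k⁺(x) = gamma · u_b⁰(x)`, `k⁻ = gamma · u⁰`: the binding-rate map is
  proportional to the initial hindered excess, so bright steady-state
  regions are modeled as strongly hindering; `gamma` is the single
  proportionality constant. The initial state is an exact reaction
  equilibrium by construction.
* At the nuclear membrane Γ_M the concentration may **jump**; the diffusive
  flux through the membrane follows J = p [[u]], with permeability `p`
  (um/s). The cell boundary is impermeable.

The discretization uses fully discontinuous piecewise-linear elements on an
interface-conforming triangulation (the membrane is a union of element
edges). Interior edges carry the standard symmetric consistency terms plus
a (sigma/h) Nitsche penalty; membrane edges carry *only* the p-coupling —
the interface condition is the physics there, not a continuity constraint.
Time stepping is backward Euler with the bleach-on and bleach-off systems
factorized once and reused. Parameters are estimated by Nelder–Mead simplex
search over log-parameters on the misfit

    E = (1/N) Σ_i ∫_Ω |u(t_i) + u_b(t_i) − c_g(t_i)|² dx,

where the goal functions c_g interpolate the blurred, normalized frames.
For validation, every pixel's decay can be fitted with a
stretched/compressed exponential I(t) = I0·exp[−(t/tau)^(1/h)] + Ib and
summarized as amplitude/time-constant/heterogeneity/rate-coefficient maps.

## Worked example

A forward FLIP simulation at the default acquisition protocol (2.6 s frame
period = 0.8 s bleach + 1.8 s recovery, 50 frames, snapshots 2.0 s into
each frame):

```r
library(flipdg)

geo <- syntheticGeometry(
  cellEllipse    = list(center = c(7.5, 7.5), semiAxes = c(6, 5)),
  nucleusEllipse = list(center = c(7.5, 7.5), semiAxes = c(2.5, 2)),
  bleachCenter   = c(11.5, 7.5))      # 1.64-um bleach disk in the cytoplasm

mesh <- triangulateGeometry(geo, targetEdgeLength = 0.45)
mesh
#> TriMesh: 1624 triangles (840 nucleus, 784 cytoplasm, 20 bleach-flagged)
#>   2464 edges: 56 outer, 2352 interior, 56 membrane
#>   areas: cell 94.041, nucleus 15.673 um^2; membrane 14.172 um

space  <- dgSpace(mesh)
c0     <- ifelse(dofRegion(space) == "nucleus", 0.85, 0.35)  # nuclear enrichment
params <- modelParameters(alpha = 16.1, beta = 35.6, gamma = 0.319, p = 0.111)
system <- assembleSystem(space, params, rateMaps(c0, params@gamma))
traj   <- runFlip(initFieldsFromFrame(c0), system, bleachSchedule())
traj
#> FlipTrajectory: 50 snapshots on 4872 dofs, t in [2.00, 129.40] s
#>   total mass 40.7506 -> 0.588709
```

Over the 50 frames the nuclear mean intensity falls from 0.836 to 0.028
while the cytoplasmic mean falls from 0.260 to 0.002: the membrane
(p ≈ 0.1 um/s) visibly delays nuclear fluorescence loss relative to the
cytoplasm, which is the physiological signature FLIP exploits.

Calibration runs the same forward model inside a downhill-simplex search:

```r
goals <- goalSeriesFromTrajectory(traj)   # or goalSeriesFromStack(stack, space)
fit <- calibrateFlip(goals, space, bleachSchedule(), c0)   # guess (25, 20, 0.5, 0.05)
```

and returns the estimated `ModelParameters`, the misfit, and the
per-iteration trace of the best simplex vertex. Pixel-wise validation:

```r
syn  <- synthesizeFlipStack(params, geo, bleachSchedule(nFrames = 30L))
maps <- fitStrExpStack(precondition(syn$stack), syn$stack@cellMask)
strExpRegionSummary(maps, syn$labelMask)   # tau_median: nucleus ~39 s vs cytoplasm ~9 s
```

A shell front end with the same functionality is installed at
`inst/scripts/flipdg` (`make-synthetic`, `simulate`, `calibrate`, `strexp`;
flat `key = value` config files plus `key=value` overrides).

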