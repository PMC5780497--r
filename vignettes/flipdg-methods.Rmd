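---
title: "Modeling and calibrating FLIP sequences with a discontinuous Galerkin membrane model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and calibrating FLIP sequences with a discontinuous Galerkin membrane model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model and its assumptions

`flipdg` models a fluorescence-loss-in-photobleaching (FLIP) acquisition as
a two-species reaction–diffusion system on a segmented cell domain
Ω = Ω_N ∪ Ω_C (nucleus and cytoplasm) separated by the nuclear membrane
Γ_M, with a circular bleach region Ω_B in the cytoplasm. The observed
intensity c = u + u_b is split into a freely diffusing pool u and a
non-diffusing, locally hindered pool u_b:

$$u_t = \nabla\cdot(\alpha\nabla u) + k^- u_b - k^+(x)\,u
        - \chi_{\Omega_B}\,\theta(t)\,\beta\,u,\qquad
  (u_b)_t = k^+(x)\,u - k^- u_b - \chi_{\Omega_B}\,\theta(t)\,\beta\,u_b.$$

The assumptions behind this structure:

* **Hindrance as mass action.** Spatial heterogeneity of the steady-state
  intensity is attributed to reversible local trapping, not to a spatially
  varying diffusion coefficient. The binding-rate map is tied to the first
  (preconditioned) frame: $k^+(x) = \gamma\,u_b^0(x)$ and
  $k^- = \gamma\,u^0$, with $u^0 = \min_x c^0(x)$ the uniform free
  background and $u_b^0 = c^0 - u^0$ the hindered excess. This makes the
  initial state an exact equilibrium of the reaction subsystem, nodewise in
  the discrete system (both sides of the identity are integrated with the
  same quadrature rule, so the no-bleach run preserves the initial state to
  solver round-off — a property the test suite asserts at 1e-10).
* **One effective bleach rate.** The photophysical chain (intrinsic bleach
  rate and ground/excited equilibrium) enters FLIP data only through the
  product, so only the effective rate β (1/s) is parameterized; the factors
  are not separately identifiable. Both pools bleach at the same rate while
  the laser is on.
* **Semipermeable membrane.** Across Γ_M the concentration may jump, and
  the flux follows Fick's law integrated across the membrane,
  $J = p\,[\![u]\!]$, with permeability p in um/s. The outer cell boundary
  is a zero-flux wall (no export of the tagged protein on the experiment's
  timescale).
* **Binary laser.** θ(t) is 1 during the bleach interval of each frame and
  0 during recovery/scanning. The image is treated as an instantaneous
  snapshot at a configurable offset inside the frame (default 2.0 s, i.e.
  late recovery, when the scan happens); scan-time integration over the
  1.8 s recovery window is not modeled.

## Parameters

| parameter | meaning | units | typical value / default |
|---|---|---|---|
| `alpha` | diffusion coefficient of free pool | um²/s | 16.1 (GFP-scale default of the generator) |
| `beta`  | effective bleach rate in Ω_B | 1/s | 35.6 |
| `gamma` | binding-rate proportionality | 1/(intensity·s) | 0.319 |
| `p`     | membrane permeability | um/s | 0.111 |
| `tBleach`, `tRecover` | frame timing | s | 0.8, 1.8 |
| `dt` | backward-Euler step | s | 0.2 |
| `tOffset` | snapshot offset in frame | s | 2.0 |
| `sigma` | Nitsche penalty | — | 20·α·(degree+1)² |
| `blurRadiusPx` | preconditioning Gaussian SD | px | 1 |

The generator defaults are the realistic GFP-scale operating point used
throughout the tests; probe presets (`probePreset`) rescale `alpha` by the
Stokes–Einstein relation (D ∝ 1/R) from the GFP reference (R = 2.42 nm) to
Fl-Cys (0.67 nm), ubiquitin (1.69 nm) and maltose-binding protein
(2.85 nm), and reduce `p` with size (1/R). The true size dependence of
passive nuclear-pore passage is much steeper than 1/R; the presets are
meant for ordering comparisons (larger probe ⇒ slower nuclear loss), which
the tests assert as strict orderings, not for absolute permeability
prediction.

# Discretization

## Function space

We use fully discontinuous piecewise-**linear** elements on triangles
(3 dofs per element, none shared). Descriptions of this construction
sometimes say "piecewise bilinear", which is not a standard space on
triangles; linear elements are the standard choice, and the observed
convergence orders (spatial L² order ≈ 2, temporal order ≈ 1, both computed
by `verifyConvergence()` and asserted in the tests) are those expected for
degree-1 elements with backward Euler.

## Interior-penalty form

On interior edges the div–grad operator gets the symmetric interior-penalty
treatment: the two consistency terms plus a penalty (σ/h)∫[[u]]·[[v]] ds,
where h is the mean of the two adjacent elements' diameters (longest edge).
σ defaults to 20·α·(degree+1)² — coercivity only requires σ "large enough",
so the default is validated at assembly time by checking the smallest
eigenvalue of the assembled diffusion operator on a coarse probe mesh
(threshold −1e-10 relative). Membrane edges carry **no** penalty and no
consistency terms: only the coupling p∫[[u]]·[[v]] ds, because the
interface condition *is* the physics there — penalizing the jump would
wrongly force continuity. Outer-boundary edges carry nothing (natural
zero-flux condition). Quadrature: exact closed forms for all volume and
edge integrands of the bilinear forms; the spatially varying k⁺ mass matrix
uses the 3-point edge-midpoint rule (exact for quadratics), deliberately
the same rule as the plain mass matrix so the reaction-equilibrium identity
holds exactly in the discrete system.

## Time stepping and linear algebra

Both equations are advanced fully implicitly and monolithically: one sparse
2n×2n backward-Euler solve per step. The step matrix exists in exactly two
versions (bleach on / off); each is LU-factorized once per run and the
factors reused across all steps. One step of iterative refinement (default)
drives the per-step solve error to near round-off, which is what lets
650-step steady-state and conservation runs stay below 1e-10 relative
drift; calibration forward solves switch refinement off for speed, since
there the misfit differences dominate. Backward Euler is L-stable, so large
steps damp rather than oscillate (asserted for dt up to 10 s).

# Meshing

The triangulator is interface-conforming by construction rather than by
constrained Delaunay: the nucleus is meshed as an O-grid (a structured
square core plus radial transition rings that blend the square boundary
onto the nucleus outline — no centre or corner singularity), and the
cytoplasm as a structured annulus along rays from the nucleus centroid.
Both parts share the membrane-ring vertices, so Γ_M is exactly a union of
element edges. Ring quads are split along their shorter diagonal, which
keeps corner quads shape-regular; meshes with a minimum angle below 20°
(configurable) are rejected, since the penalty scaling assumes shape
regularity. Outlines are polygons; curvature is resolved by angular
sampling at the target edge length. The construction requires both outlines
to be star-shaped about the nucleus centroid — true for typical segmented
cell shapes, and checked with a clear error otherwise; strongly non-convex
cells would need an external mesher, whose output can be imported through
the Gmsh MSH 2.2 reader. The bleach disk is represented by flagging
elements whose centroid falls inside it (the bleach term is a volume
source, so no geometric conformity is needed there).

# Imaging conventions

* Raster row 1 is the top of the image; mesh coordinates are physical um
  with the origin at the lower-left corner and y up. The conversion
  y = (nrow − row + 0.5)·pixelSize is applied in exactly one place each
  direction and is covered by ramp-interpolation tests.
* Preconditioning: "blur radius of one pixel" is interpreted as a Gaussian
  with standard deviation 1 px (a common imaging convention; the term is
  not precise). The blur is mask-normalized — blur(f·m)/blur(m) — so
  background outside the cell cannot bleed in; the whole stack is then
  divided by the maximum of the first blurred frame inside the mask, which
  puts the first frame in [0, 1] and makes the normalization idempotent.
* Goal functions are built by nodal interpolation of the blurred frames
  (each DG node takes the bilinearly interpolated image value at its
  location). A per-element least-squares projection would differ at second
  order in the pixel size, which is negligible at 0.05-um pixels.
* The synthetic generator forward-simulates from a steady pattern (default
  0.85 in the nucleus, 0.35 in the cytoplasm — nuclear enrichment with a
  uniform free background), rasterizes the snapshots, and adds seeded
  additive Gaussian noise clipped at zero (a Poisson option exists behind a
  flag). It emulates the acquisition geometry, timing, nuclear retention,
  and pixel noise; it does **not** emulate intra-compartment intensity
  texture, scan-time integration, detector offsets, or cell motion — so
  passing recovery tests demonstrates correctness of the inference
  machinery on data matching the model, not robustness to real-microscope
  artifacts.

# Calibration

The estimation problem is an argmin over strictly positive (α, β, γ, p),
so the simplex search runs over log-parameters — positivity by
construction, no penalties. The initial simplex perturbs each coordinate by
0.05 in log space (≈5%); nothing in the method description fixes this, and
5% is a conventional simplex seed step. The iteration stops when both the
simplex x-spread and the value spread E₅−E₁ fall below their tolerances
(both default 1e-4), matching the standard dual stopping rule. Each misfit
evaluation is a full forward solve: the candidate parameters rescale cached
unit matrices (D is proportional to α because σ ∝ α; P is linear in p, the
reaction blocks linear in γ, the bleach block linear in β), so no
re-assembly happens inside the search, only two LU factorizations per
candidate. A failed forward solve scores +∞ and the search continues; a
non-finite misfit at the initial guess aborts with a diagnostic. The
engine is implemented in-package because the trace (best vertex, E₁, E₅−E₁
per iteration) and the dual tolerance rule are part of the reporting
contract; it is cross-checked against `stats::optim`'s Nelder–Mead on the
Rosenbrock function in the tests.

Problem sizes: the recovery studies run on a ~430-element mesh with 20
frames (260 time steps per evaluation), where a full calibration takes a
few minutes; the forward-simulation checks run on a ~1600-element mesh with
50 frames. These sizes were chosen so the whole verification suite runs on
a laptop-class single core; the solver itself has no size-specific logic.
Noise-free self-consistent goals are recovered to ≪1% per parameter;
with 0.01 additive noise the recovery tolerances asserted are 15% for
(α, β, γ) and 30% for p — the permeability is the most weakly identified
parameter because it only acts through the (small) membrane jump.

# Stretched-exponential validation

Pixel decays are fitted with I(t) = I₀·exp[−(t/τ)^(1/h)] + I_b by bounded
Levenberg–Marquardt (`minpack.lm`), with 0 < h ≤ 2, τ > 0, I₀ > 0,
I_b ≥ 0. Initialization: I_b from the mean of the last 10% of frames, I₀
from the first value, τ from the 1/e crossing, h = 1 — robust standard
choices; the reference pixel-wise fitting tools do not document theirs.
Non-converged or flat pixels are flagged and excluded from the fit mask
rather than silently returned. The rate-coefficient map
k(x,t) = (1/(hτ))·(t/τ)^{1/h−1} is the instantaneous decay rate of the
normalized fit: constant for h = 1, increasing in t for h < 1 (compressed,
delayed-then-accelerating loss — the signature of membrane-limited nuclear
loss), decreasing for h > 1 (stretched). At t = 0 the expression is
singular for h > 1, so zero times are rejected. Fits run on the
preconditioned stack, matching the pipeline the maps are compared against.

# Degenerate inputs and tie-breaks

* `initFieldsFromFrame` requires c⁰ ∈ [0, 1] and directs the caller to
  `precondition()` otherwise; a constant first frame yields k⁺ ≡ 0 (no
  hindrance anywhere), which is legal.
* `rateMaps` requires min(c⁰) > 0: a zero background would make k⁻ = 0 and
  the hindered pool a permanent sink.
* Pixels exactly on a membrane-adjacent element edge rasterize from
  whichever incident element is visited last; membrane discontinuities are
  preserved to within one pixel.
* `updateSystem` (but not the public constructor) accepts zero β, γ or p so
  the diagnostic limits — sealed membrane, laser off, inert reaction — are
  expressible on an assembled system.

# Known limitations

* 2-D only, single cell, static geometry; no drift/registration.
* The hindered pool does not diffuse, and hindrance causes are not
  mechanistically resolved (mean-field mass action).
* Membrane transport is passive; receptor-mediated (active) transport would
  need a different interface law.
* The mesher requires star-shaped outlines (import external meshes
  otherwise).
* TIFF storage quantizes intensities at 2⁻³²; out-of-range maps are stored
  affinely rescaled with the scaling recorded in a JSON sidecar.
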