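---
title: "Methods: digital-twin biomechanics for fracture-fixation revision planning"
author: "FractureTwin authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: digital-twin biomechanics for fracture-fixation revision planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FractureTwin)
```

# Scope and model

FractureTwin compares fracture-fixation treatment variants on idealized
bone-implant constructs. The chain mirrors a clinical digital-twin
workflow: a greyscale volume standing in for a CT scan is segmented into
tissue and implant regions by greyvalue thresholds, converted to a
labeled tetrahedral mesh, given isotropic linear-elastic materials
(CT-derived for bone, fixed for implants and callus), solved under a
static peak joint load with the distal end fixed, and evaluated through
two lenses: the mechanobiological *healing window* of the fracture
callus and the von Mises stress of the implant. A separate rigid-body
module sweeps a carpal unit through radial/ulnar deviation and detects
impingement for joint-realignment scenarios.

Everything downstream of image acquisition is computed; nothing upstream
is. Patient CT volumes, motion capture and musculoskeletal load
estimates are replaced by a parametric construct generator and a
configurable static load library, because no such patient data are
available to ship. Consequences of that substitution are discussed under
*What the synthetic data do and do not show*.

# The synthetic construct generator

`constructSpec()` describes an idealized long bone along +z (distal end
at z = 0): a cortical tube (outer radius, cortical thickness), a
trabecular interior, a transverse fracture gap of configurable width
filled with soft callus, and optional implants — an intramedullary nail
(cylinder in the medullary canal), an augmentative plate (partial
cylindrical shell flush with the periosteal surface), and transverse
screws (cylinders through the shaft). Region membership is evaluated
analytically at voxel centers with precedence
implant > callus > cortical > trabecular > background, which keeps the
ground truth exact for testing; there is no anti-aliasing. Greyvalues
are per-region levels plus i.i.d. Gaussian noise with an explicit seed,
so identical spec and seed give bit-identical volumes.

Default greyvalues (HU-like) are background −1000, callus 50, trabecular
300, cortical 1500, screw 2400, plate 2700, nail 3000. The ordering
mimics clinical CT; the three metal levels are deliberately distinct so
that thresholding can recover *which* implant a voxel belongs to, and
adjacent levels sit at least 300 HU apart — 12 standard deviations at
the default noise of 25 HU — so misclassification under the default
noise is negligible (the Gaussian tail bound is tested at three noise
levels). A single shared "metal" level would make the ground-truth label
map unrecoverable by any threshold rule once two implant components are
present.

The default construct is a tibia-scale shaft: 200 mm long, 12 mm outer
radius, 4 mm cortex, a 4 mm mid-shaft gap, 1 mm voxels (roughly half a
million tetrahedra after meshing). The fracture gap is a plane-parallel
slab; clinical callus morphology is irregular and manually delineated,
which cannot be reproduced from published information, so the slab is an
explicit stand-in.

# Segmentation

`thresholdSegment()` assigns each voxel the unique half-open interval
[lower, upper) of a validated threshold table; intervals must tile the
whole greyvalue axis, so every voxel is labeled exactly once and a
boundary value belongs to the interval it starts. The default table
places boundaries at midpoints between the default greyvalue levels,
making noise-free segmentation the exact inverse of the generator — that
identity is the module's oracle test. No morphological cleanup runs by
default (it would break the oracle); `largestComponentFilter()` is
available as an explicit post-pass for noisy data. Externally produced
label maps (e.g. manual clinical segmentations) enter through
`asLabelMap()`, bypassing thresholds.

# Meshing

`voxelsToTetMesh()` subdivides every foreground voxel into the six Kuhn
tetrahedra sharing the voxel's main diagonal. The subdivision is
translation-invariant, so faces shared by neighboring voxels carry
matching diagonals and the mesh is conforming by construction; nodes are
deduplicated by exact integer grid arithmetic (a doubled-index grid for
the mid-edge nodes of quadratic elements), never by floating-point
tolerance. Mesh volume therefore equals foreground voxel volume exactly,
per region, which the tests assert to rounding error. A body-fitted
adaptive mesher in commercial software is not reproducible or testable
in this setting; the voxel mesh is deterministic and exactly auditable,
at the price of stair-stepped surfaces.

Both 4-node (linear, constant-strain) and 10-node (quadratic, C3D10
ordering) tetrahedra are supported. Linear elements are the default
because constant-strain closed forms (bar, patch test) are exactly
representable, which makes solver verification sharp; quadratic elements
are substantially more accurate in bending at the same voxel size (the
cantilever suite measures both). Named cuboid node sets
(`defineCuboidNodeset()`, closed-box membership) mark the distal
constraint and proximal load regions, conventionally `DISTAL_FIX` and
`PROXIMAL_LOAD`.

# Materials

Bone moduli come from the greyvalue of each element's parent voxel
through a linear density ramp with a floor and a power law:
rho = max(a + b·HU, rho_min) in g/cm^3 and E = c·rho^d in MPa, with
defaults a = 1.0, b = 0.001, rho_min = 0.05, c = 6850, d = 1.49 — a
published apparent-density power law anchored so that 0 HU maps to
water-equivalent density. The clinical workflow this emulates cites
"established approaches" without printing coefficients, and calibration
phantoms are not routinely available, so the calibration is explicit
configuration, recorded in every report's provenance block.

Fixed-property regions: soft callus E = 3 MPa, nu = 0.4 (the soft-callus
convention of the tissue-differentiation literature); titanium-alloy
implants E = 110 GPa, nu = 0.3 (steel at 200 GPa is available as an
alternative); bone Poisson ratio 0.3. On the voxel mesh each element
maps to exactly one voxel, so all six tetrahedra of a voxel carry
identical properties — interpolation ambiguity never arises.

# The finite element solver

`assembleAndSolve()` solves static linear elasticity in a fixed
mm-N-MPa unit system. Dirichlet constraints (default: all axes clamped
to zero on the distal set; per-node prescribed values are supported,
which is how the patch test drives a linear field) are eliminated from
the system; each Neumann total force is split equally across its node
set, matching the cuboid-reference-area convention — by Saint-Venant's
principle the difference from a consistent traction decays away from the
end, and the quantities of interest live at mid-shaft. For verification
problems where end effects are the point, `faceTributaryWeights()`
provides the consistent uniform-traction weights (face area thirds on
corner nodes for linear elements; on mid-edge nodes for quadratic ones),
which makes the axial bar exact to machine precision.

All region interfaces are perfectly bonded (shared nodes, no contact or
friction): the emulated workflow meshes each treatment state as one
monolithic model. Element stiffness uses the closed-form constant-strain
matrix for linear tets and a 4-point degree-2 Gauss rule (exact for
straight-sided elements) for quadratic tets, assembled in compiled code
into a sparse symmetric matrix. Systems up to 120 000 free degrees of
freedom are factorized directly (sparse supernodal Cholesky); larger
systems switch to conjugate gradients preconditioned with an incomplete
Cholesky IC(0) factorization at a fixed relative-residual tolerance of
1e-10, with a progressive diagonal shift on factorization breakdown.
The switch exists because the direct factor of the full-resolution
construct (~300 000 dof on a long cylinder) has a memory footprint in
the multi-GB range, while IC(0)-PCG solves it in tens of seconds within
a few hundred MB; the threshold was sized to keep the direct branch
comfortably inside a few GB. Under-constrained systems are rejected
before assembly with the exact count of unrestrained rigid-body modes
(rank of the rigid-mode basis restricted to the constrained dofs).

Strain is recovered per element — the constant value for linear
elements, the average of the four integration-point values for
quadratic ones — and stress follows from the isotropic law with that
element's (E, nu). Reported maxima are raw per-element values; no nodal
averaging or smoothing is applied, so peaks are conservative and
mesh-resolution-dependent in the same way for both variants of a
comparison.

# Healing-window evaluation

For each callus element the octahedral shear strain
gamma_oct = (2/3)·sqrt((e1−e2)² + (e2−e3)² + (e3−e1)²) and the
volumetric strain eps_vol = e1+e2+e3 are computed from tensor invariants
(3·tr(eps²) − tr(eps)² under the root), which is algebraically identical
to the principal-strain form and frame-invariant by construction.
Elements are classified into nested zones of the (gamma_oct, eps_vol)
plane, innermost first, with ≤ on upper bounds so boundary states take
the lower-strain zone:

| zone | rule (defaults) |
|---|---|
| understimulated | gamma_oct < 0.0025 and abs(eps_vol) < 0.0025 |
| intramembranous | gamma_oct ≤ 0.05 and abs(eps_vol) ≤ 0.05 |
| endochondral | gamma_oct ≤ 0.15 and −0.15 ≤ eps_vol ≤ 0.05 |
| excessive | everything else |

The healing window is intramembranous plus endochondral. The exact
numeric limits used in the emulated clinical workflow are deferred to
the mechanobiology literature rather than printed, so these defaults —
which mirror the ±5 % / ±15 % structure of that literature, with
endochondral ossification tolerating more compression than tension —
are explicit, configurable stand-ins embedded in every report. Because
the source workflow reports fractions sometimes by volume and sometimes
by element count, both weightings are always computed; on the uniform
voxel mesh they coincide exactly.

Implant assessment uses the von Mises stress sqrt(3/2·s:s) of the
deviator s, with the per-region peak and its element id
(lowest-id tie-break) reported by `peakStress()`.

# Range-of-motion sweeps

The wrist scene idealizes the distal radius articular surface as a
spherical cup, the proximal carpal unit (scaphoid, lunate, triquetrum as
one rigid body) as a sphere carried at a fixed offset from the rotation
center, and malalignment as a prominence indenting the cup over a
limited angular band with quadratic falloff. Without a prominence the
radial clearance (default 2 mm) guarantees a contact-free sweep; a
prominence taller than the clearance produces impingement near its band.
Because the carpal sphere subtends a finite angle at the rotation
center, first contact occurs several degrees before the band center —
the tests therefore compare the sweep against a dense brute-force oracle
on the same meshes rather than against the nominal band position.

Contact is exact triangle-triangle intersection (separating-axis test
over the 17 candidate axes, so coplanar pairs are handled), preceded by
an axis-aligned bounding-box prefilter; an optional clearance epsilon
uses the exact triangle-triangle distance (vertex-face and edge-edge
minima). All bodies are rigid for the contact query — the emulated
workflow's contact finding is kinematic, and elastic wrist FE is out of
scope. The default sweep covers ±40° in 0.5° steps, bracketing the
clinical targets of 20-30° radial and 30-40° ulnar deviation; reported
limits are the last contact-free sampled angle per direction, so they
are accurate to one step by construction. Contact in the neutral
position is reported as a state, not an error, since it is a clinically
meaningful finding.

# Shipped cases and loads

Five seeded case definitions (YAML under `inst/extdata/cases/`, editable
and overridable) wire the stages together; baseline and revision differ
only in the intended treatment parameter:

1. nail exchange 8 mm → 11 mm on the tibial construct;
2. augmentative plate on a humerus-scale construct (160 mm, 10 mm
   radius) with a retained nail;
3. augmentative plate on a femur-scale construct (200 mm, 14 mm
   radius);
4. transverse strain-reduction screws bracketing the gap under a
   torsion-dominant load;
5. the wrist realignment sweep (prominence removed postoperatively).

Patient-specific musculoskeletal loads are not available, so the load
library is explicit configuration: the lower-extremity default is
1500 N axial compression plus 150 N transverse at the proximal cuboid
(a walking-peak stand-in of roughly twice body weight with a bending
component), the humerus analogue uses 350 N + 100 N, the femur analogue
1800 N + 200 N, and the torsional case applies an 8 N·m torque — within
the range reported for tibial torsion during gait — as an equilibrated
force couple over the two halves of the proximal cuboid, plus 500 N
axial. Magnitudes are recorded in every report.

Because clinically reported magnitudes for such revisions (peak implant
stresses of hundreds of MPa falling by factors of 3-5, healing-window
fractions shifting by several percent) arise from patient-specific
geometry and loads that are not publicly available, the shipped cases
are *directional* analogues: the one quantitative acceptance claim is that the 8 → 11 mm
nail exchange reduces peak nail von Mises stress by at least half, which
the idealized construct reproduces (the slender-beam section-modulus
ceiling for that change is 100·(1 − (8/11)³) ≈ 61.5 %; load sharing
with the bone keeps the FE value below the ceiling).

# Numerical choices and problem sizes

* Solver tolerances: direct Cholesky to machine precision; PCG relative
  residual 1e-10; equilibrium residual asserted ≤ 1e-8.
* Determinism: the only randomness is the generator noise, driven by an
  explicit seed; reports are byte-identical across reruns with the same
  seed, and the test suite asserts it.
* Test problem sizes: unit and property tests run on 40-60 mm constructs
  at 2 mm voxels (seconds); the acceptance comparison runs the full
  200 mm construct at 1 mm voxels (~540 000 elements, ~300 000 dof,
  about a minute per variant), sizes chosen so the complete suite runs
  on a single CPU in minutes.
* Ties and boundaries: half-open threshold intervals; closed node-set
  boxes; ≤ on zone upper bounds; lowest-element-id tie-break for peak
  stress.
* Degenerate inputs are rejected with named invariants (infeasible
  geometry, empty foreground, empty node sets, under-constrained
  systems, asymmetric tensors, empty callus).

# What the synthetic data do and do not show

The generator provides exact ground truth, so passing tests demonstrate
that segmentation inverts the imaging model, meshing conserves volume,
the solver reproduces closed forms and convergence rates, the
classifiers match their definitions, and treatment effects point in the
mechanically expected direction at realistic magnitudes. They do not
demonstrate accuracy on real patients: real CT has beam hardening, metal
artifacts and partial-volume effects that threshold segmentation alone
would not survive; real fracture geometry, callus morphology and
musculoskeletal loads are patient-specific; and linear elasticity with
perfect bonding omits contact, friction and material nonlinearity.
Predictions of this kind are decision support, not measurement.

# Known limitations

Single static load step (no load histories or fatigue); no contact
mechanics; no tissue differentiation over healing time (the classifier
is a snapshot criterion); isotropic bone; stair-stepped voxel surfaces;
the wrist module is purely kinematic. The `fracture-twin` command-line
chain of the emulated workflow is represented by the exported R
functions and `scripts/acceptance.R` rather than a shell tool.
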