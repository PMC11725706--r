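---
title: "Methods: rigid-body modeling of fossil archosaur locomotion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rigid-body modeling of fossil archosaur locomotion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleomech)
```

`paleomech` implements the numerical core of whole-body musculoskeletal
modeling for extinct archosaurs: segment mass properties, joint coordinate
systems and forward kinematics, range-of-motion (ROM) proxies, muscle
moment arms by tendon excursion, whole-body centre-of-mass (COM) statics,
allometric mass estimation, and a linear-discriminant posture vote. This
vignette documents the models, their assumptions, the tunable parameters,
and the numerical choices, in that order. Everything empirical stated here
is computed by the package's own test suite or `scripts/acceptance.R`.

## Coordinate conventions

A concrete global frame is required because anatomical directions alone do
not define one: **+X craniad, +Y left, +Z dorsad**, lengths in meters,
masses in kilograms, densities in kg/m³. Angles are degrees at every user
interface and radians internally. "Craniad offset" of the COM is its ΔX
from the acetabular midpoint; "ventrad offset" is −ΔZ.

## Mass properties from watertight meshes

For a closed, outward-oriented triangle surface, the volume integrals of
1, $x_i$, and $x_i x_j$ over the enclosed solid are sums of closed-form
polynomials over signed origin tetrahedra (one per face). `mass_properties()`
evaluates these exactly — there is no discretization error, which is why a
unit cube returns principal inertias of exactly $m/6$. Construction-time
validation requires every edge to be shared by exactly two faces and
rejects zero-area faces; a negative signed volume (inward orientation) is
repaired by flipping the winding, with a logged message rather than an
error, since inverted exports are common and unambiguous to fix.

The independent check in the test suite is a column-integration oracle: a
200×200 grid of vertical rays, each ray's surface crossings paired into
inside intervals and integrated analytically along z. On seeded star-shaped
test solids the two methods agree to ~2×10⁻⁵ relative volume, far inside
the 0.5%/1% bands the tests assert.

Composites (`composite_properties()`) rotate part inertias and apply the
parallel-axis theorem about the combined COM; `mirror_body()` conjugates
the inertia by the reflection across y = 0. Cavity-bearing segments are
handled as signed-density terms: a cavity of density ρ_cav inside tissue of
density ρ contributes (ρ_cav − ρ) times its own integrals, which makes a
cavity at tissue density cancel identically and keeps disjoint cavities
additive.

## Hoop lofting

Body segments are octagonal cross-section stacks lofted into watertight
solids. Numerical choices: side quads split deterministically along the
(i, i+1) diagonal; end caps fanned about the hoop centroid; stations used
only for ordering, so hoops may follow curved body axes. For identical
hoops the loft is a prism and its volume equals shoelace area × length to
1×10⁻¹² relative — this exactness is a regression guard on the whole
triangulation scheme. Linear tapers are not exactly conical frusta (the
side triangles are planar), but agree with the frustum formula and the
column oracle to well under 0.5%.

Default densities are 1000 kg/m³ for tissue and 0 for air cavities —
the published workflow this emulates does not print its density table, so
the conventional near-water value is used and both are overridable per
segment. No soft-tissue "hoop expansion" factor is modeled: in the source
workflow that step is an artistic judgment applied when the hoops are
drawn, i.e. upstream of these inputs.

## Joint frames, kinematics, and ROM

Articular surfaces are summarized by least-squares primitives: planes
(total least squares via the covariance eigendecomposition), spheres
(linear algebraic fit), cylinders (axis direction optimized over spherical
angles with an inner algebraic circle fit, multi-started from the
covariance eigenvectors — deterministic, no RNG), and ellipsoids
(homogeneous quadric fit by SVD, centered and scaled for conditioning).
Fitted directions get a deterministic sign (positive dot with +X, ties
broken by +Y then +Z) so repeated runs and mirrored data give reproducible
frames; equivariance under rotation therefore holds up to that sign pin,
which is what the property tests assert. An ellipsoid's primary axis is its
longest; a sphere has no intrinsic axis, so `build_acs()` requires an
explicit primary for spheres rather than inventing one.

Joints allow rotations only, applied intrinsically in x→y→z order about the
shared JCS: z = flexion–extension (extension positive), y =
ab/adduction, x = long-axis rotation (external positive). Hips and
shoulders carry three DOFs; all other limb joints one. Forward kinematics
composes $P\,R_x R_y R_z\,P^{-1}$ down the tree, where $P$ places the JCS in
the global reference pose, so the all-zero pose reproduces the reference
placements exactly (to machine precision, not approximately). Cartilage
offsets are fixed translations added to the JCS origin at model build; hip
and ankle default to zero because those joints articulate tightly.

ROM limits are inclusive intervals per DOF that must bracket 0°.
`rom_scan()` is an explicitly-labeled *proxy* for the published
judgment-based procedure: it sweeps one DOF from 0° on a grid (default 1°)
and stops at triangle–triangle contact between the segment meshes
(excluding faces on the declared articular patches) or when the articular
patch centroids separate beyond a gap threshold. The gap default is 5 mm —
the field's notion of "excessive disarticulation" is subjective and no
printed value exists, so this is the package's choice. Because the
judgment-based published limits are not reproducible from geometry alone,
they ship verbatim as `riojasuchus_rom.yaml` (hip −65/55° FE, −10/70°
ab/adduction, ±50° LAR; knee −110/0°; ankle −50/30°; MTP3 −80/50°) and the
scanner is validated against constructed geometries with analytic contact
angles instead.

## Muscle paths and moment arms

A muscle is an ordered polyline of points bound to segments, plus optional
wrap surfaces. Cylinder wrapping is solved obstacle-set style in the plane
perpendicular to the axis: tangent–arc–tangent length
$\sqrt{d_1^2-R^2}+\sqrt{d_2^2-R^2}+R\varphi$, developed to 3D by
unrolling (adding the axial travel in quadrature). The engagement test is
strict penetration of the straight span; grazing tangency counts as *not*
wrapped, which makes path length continuous across the boundary (asserted
to <10⁻⁶ m in the tests). The `side = "long"` active-arc flag forces the
far-side arc regardless of penetration, which is how anatomically
constrained, fully-wrapped tendons (e.g. around a joint pulley) are
modeled; such a tendon's moment arm about a coaxial hinge is exactly the
cylinder radius, one of the closed-form checks.

Moment arms use the tendon-excursion definition $r = -\,dL/d\theta$
(θ in radians), evaluated by central difference with default half-step
h = 0.25°. Finite differencing is chosen over geometric (cross-product)
formulas because it remains valid for wrapped paths; the error against the
law-of-cosines hinge closed form is O(h²) (halving h shrinks it ~4×) and
below 0.1% at the default step. Sign convention: positive r generates a
moment increasing the DOF's angle, so positive about z is extensor.
ROM limits are deliberately not enforced during sweeps so curves remain
continuous past the limits. `classify_action()` labels curves by sign with
a 10⁻⁴ m dead band and reports interpolated zero crossings for switching
muscles.

The shipped `riojasuchus_muscles.csv` transcribes the published 37-row
hindlimb origin/insertion topology (bone + region + inference level). It
records topology, not coordinates: attachment coordinates exist only in
the deposited model, so model files and the synthetic generator place
their own.

## Whole-body statics and allometric mass

`whole_body_com()` composites posed segments and reports offsets from the
posed acetabular midpoint; the craniad offset is also normalized by the
gleno-acetabular distance, the standard dimensionless COM for this
literature. The bipedal test is deliberately minimal sagittal statics:
feasible iff the craniad COM offset lies inside the feet's craniocaudal
support interval (inclusive), with a signed margin. Mediolateral support
polygons and dynamic balance are out of scope. The "realistic" preset pose
is −10° flexion at hip, knee, ankle and elbow and +10° at shoulder and
wrist.

Allometric mass uses the stylopodial-circumference regression
$\log_{10} BM[\mathrm g] = 2.749\,\log_{10}(C_h + C_f[\mathrm{mm}]) - 1.104$
with its ±25.6% prediction-error band; the shipped circumferences
(39 + 66 mm) give 28.33 kg. The alternative skull-length method mentioned
in the same literature is not implemented: neither its input nor its
formula is available here.

## Posture LDA and the voting harness

The two-class discriminant is written from the Gaussian equal-covariance
formulas: class means, pooled covariance with divisor n − 2, weights
$w = \Sigma^{-1}(\mu_1 - \mu_0)$, midpoint intercept, and posterior
$\mathrm{logit}^{-1}(w^\top x - c + \log \pi_1/\pi_0)$. An optional ridge
(scaled by the mean diagonal, with an absolute floor for all-zero
covariances) handles singular fits, which otherwise error with advice to
set it. The reference implementation in `MASS::lda` serves only as an
independent oracle in the tests (posteriors agree to 10⁻⁶); it is not the
implementation. Default features are log₁₀ body mass, dimensionless COM,
and forelimb/hindlimb ratio — the exact transformation used by the prior
study lives in its own supplement, so the feature map is a replaceable
function. Priors default to class frequencies, with an equal-prior mode.

The published procedure votes one fitted model per training set over 22
sets drawn from an external 80-taxon dataset that is not redistributable
here. The harness therefore accepts *any* list of training sets, and the
synthetic generator emulates the structure: two Gaussian classes in
feature space, back-transformed to records. Reproducing the published
12/22 tally would require the original training data and is a declared
non-goal; the acceptance property instead plants a prototype target at the
bipedal class mean and requires ≥20/22 votes.

## The synthetic-data generators

`make_skeleton()` builds box-proxy bones for a pelvis–femur–crus–pes chain
(plus a two-segment forelimb) with the standard DOF scheme and the fixture
ROM attached. Default dimensions are pinned to the published skeletal
summary — femur 0.179 m, crus 0.141 m (hindlimb 0.320 m), forelimb
0.222 m, gleno-acetabular distance 0.355 m — so moment arms and COM
offsets land in a realistic size regime. Hinge muscles are placed at
seeded radii a, b ∈ [0.04, 0.10] m from the joint in the hinge plane,
recording the law-of-cosines parameters so every swept moment arm has a
closed-form truth ($r(q) = -ab\sin(\delta_0+q)/L(q)$). All generators are
pure functions of (seed, parameters): they save and restore the caller's
RNG state, and equal seeds give byte-identical bundles.

What the synthetic data do *not* emulate: real bone shapes (boxes, not
scanned surfaces), taphonomic distortion, cartilage geometry, realistic
fleshed-out segment masses, and the composition of the real LDA training
taxa. Passing tests therefore demonstrate correctness of the *computations*
on inputs with known answers — not that any biological conclusion about a
particular fossil is reproduced, which would require the deposited meshes
and model.

## Problem sizes and tolerances

The test and acceptance runs use: column oracle at 200 divisions on
~1280-face solids; icosphere subdivision 4 (5120 faces) for the analytic
sphere check; moment-arm sweeps of 9–61 grid points at h = 0.25°; LDA
samples of 50–5000 per class; and a 22-set voting ensemble of 40 records
per class per set. These sizes make every derived check deterministic at
the asserted tolerances while keeping a full run around twenty seconds.

## Known limitations

- Joints are rotation-only; no translations, no 6-DOF mobility volumes,
  no ligament constraints.
- One wrap surface acts per path span (the first engaging); stacked
  obstacles on a single span are not chained.
- `rom_scan()` tests surface intersection, so a segment mesh entirely
  inside another is not flagged; with bone-like geometries starting from a
  valid reference pose this does not arise, but degenerate proxy
  geometries can dodge it.
- Muscle force, architecture (PCSA, fiber length) and moment-generating
  capacity are out of scope: moment arms are leverages only.
- The ellipsoid fit is algebraic; for very shallow patches with heavy
  noise a geometric refinement would be more accurate.
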