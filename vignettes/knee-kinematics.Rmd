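---
title: "Lowest-point tibiofemoral kinematics: model, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lowest-point tibiofemoral kinematics: model, conventions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneetrack)
```

## The measurement problem

Weight-bearing knee kinematics are commonly measured by registering 3-D
bone or implant models to single-plane fluoroscopic images, one rigid pose
per body per frame. The quantity of clinical interest here is tibial
internal–external (I-E) rotation during everyday activities — its magnitude
at maximum flexion and its *path*: native knees concentrate rotation in the
terminal arc of extension (the screw-home mechanism), whereas a medially
conforming TKA tends to rotate progressively with flexion. `kneetrack`
implements the geometry between the registered poses and those endpoints,
plus the associated two-group statistics, and ships a synthetic generator
so that every stage can be checked against closed-form ground truth.

## Conventions

All lengths are mm and all angles degrees; there are no unit fields.
Models and analysis use a right-knee convention: x = +anterior,
y = +medial, z = +proximal in model coordinates, with the joint line at
z = 0. Left knees are handled by mirroring meshes and poses across the
sagittal plane at analysis time, so a single sign convention (internal
rotation positive) serves both sides. Pose transforms map body-local
coordinates into the lab frame; the opposite convention was rejected
because registration tools report absolute model pose.

The tibial frame axes are ML (+lateral), AP (+anterior, lying in the
reference plane) and PD (+proximal), right-handed with ML × AP = PD.

## The analysis chain

1. **Anatomic axes and flexion.** The anatomic axis of each bone is the
   chord through the area centroids of the shaft cross-sections at two
   levels from the joint line (femur 70/120 mm above, tibia 50/120 mm
   below). The area centroid of the largest closed intersection contour is
   used rather than the mean of contour vertices because the latter depends
   on mesh resolution. Flexion is 180° minus the included angle between the
   two axes directed away from the joint, so a straight limb reads 0.

2. **Femoral sagittal frame.** Spheres are fitted (algebraic least
   squares) to the two posterior condylar patches; the ML direction is the
   unit vector joining the centers. A fit RMS above 1 mm is rejected as a
   mis-identified patch.

3. **Medial plateau plane and simulated resection.** The medial articular
   plane is a total-least-squares fit to the medial plateau patch,
   re-orthogonalized to be perpendicular to the sagittal plane by a
   rotation about AP only. The resection plane starts parallel to it,
   10 mm distal to the medial condyle center, and its varus-valgus angle
   is stepped in 2° increments — in the order 0, +2, −2, +4, −4, … up to
   ±10° — until the medial and lateral condylar thicknesses (point-to-plane
   distances from the condyle centers) agree within ±0.5 mm; the first
   admissible angle wins. Nearest-to-neutral-first matches surgical intent,
   and the ±10° bound guarantees termination: outside it the search fails
   loudly with the best achieved imbalance. The pivot is the AP axis
   through the *medial* condyle center so that the 10 mm medial offset is
   preserved while tilting. The condyle "center" is the centroid of the
   articular patch — a reproducible operationalization. Thickness is a 3-D
   point-to-plane distance; a frontal-plane projected distance differs only
   for non-frontal normals and was not adopted.

   Note a structural property of these parameters: with a condylar
   separation near 46 mm, the ±0.5 mm tolerance corresponds to a
   varus-valgus band of about 1.25°, which is narrower than the 2°
   increment. Deformities whose balancing angle falls between grid points
   (near 2° and 6° of plateau varus for the default geometry) genuinely
   have no admissible adjustment, and the search reports a convergence
   failure rather than silently returning the nearest angle. The tests
   assert exactly this behaviour against an exhaustive-sweep oracle.

4. **Tibial frame.** The resection plane's intersection with the tibia is
   chained into closed contours; the origin is the center of the bounding
   box of the largest one, axis-aligned with the sagittal-frame ML/AP
   directions projected into the plane. The contour's AP extent is recorded
   as the subject's plateau depth for standardization. For TKA knees the
   reference is instead the baseplate bounding-box center, and the
   reference plane is the baseplate top surface.

5. **Lowest points and rotation.** Each condyle's position is the vertex of
   its posed patch minimizing signed distance to the reference plane, with
   ties within 0.05 mm resolved by the centroid of the tied set (a pure
   argmin is mesh-jitter sensitive on near-flat regions; the tie rule is
   what makes the lowest point stable at mm-scale tessellation). Rotation
   between two flexion angles is the angle between the medial–lateral
   lines through the condylar positions,
   `theta(f) = atan2(ap_med - ap_lat, ml_lat - ml_med)`, computed from
   *non-standardized* positions; standardized tracks are flagged and
   rejected by the rotation code, structurally enforcing that
   standardization can never alter a rotation. Since the rotation depends
   only on coordinate *differences*, translating the reference origin
   shifts all A-P positions by a constant and leaves every rotation
   unchanged — an invariance the tests check to 1e-6°. A subtlety: the
   A-P positions alone do not define an angle; the M-L coordinates of the
   same lowest points supply the second component. This is the minimal
   faithful reading of "the angle between medial–lateral lines", and the
   sign convention (internal positive = lateral femoral condyle posterior
   relative to medial, right knee) is fixed here once.

6. **Schedules, arcs, cohorts.** Activities are analyzed at fixed flexion
   schedules (step up 60/45/30/15/0°, chair rise 90/60/30/0°). When a pose
   sequence lacks an exact schedule angle, condylar positions are linearly
   interpolated between the two bracketing frames, with a nearest-frame
   fallback within 5° — a matching rule the source procedure leaves
   unstated. Arc-of-extension changes (15° arcs for step up → 4 arcs; 30°
   for chair rise → 3 arcs) telescope exactly to the rotation at maximum
   flexion. Bone-model registration repeats (three) are averaged
   coordinate-wise before profiles are built; implant (CAD) registrations
   are single-pass, reflecting their better registration precision.

## Statistics

Group comparisons default to Welch's t-test: the motivating cohort SDs at
maximum flexion (4.4° vs 12.0°) are grossly unequal, and the pooled test is
offered only as an option since the original analysis does not name the
variant. Chi-square is Pearson's without continuity correction. Quantiles
use linear interpolation between order statistics.

The power analysis is a noncentral-t computation for the Welch geometry:
standard error `sqrt(sd_a^2/n + sd_b^2/n)`, Welch–Satterthwaite degrees of
freedom, noncentrality `delta/se`. The default is **one-sided**: with
n = 25 per group, α = 0.05 and SDs 2.9°/4.6°, the one-sided minimum
detectable difference at 80 % power is ≈ 2.75°, consistent with the
targeted 2.8° detectable difference; a two-sided computation gives ≈ 3.1°.
Sidedness is configurable, and the choice is a documented interpretation,
not a claim about the original software. The analytic power is
cross-checked in the tests against direct Monte-Carlo simulation of the
Welch test (within 0.01), and `detectable_difference()` is verified to
bracket the target power definitionally.

```{r power}
spec <- power_spec()
c(power_at_2.8 = power_at(2.8, spec),
  mdd = detectable_difference(spec))
```

## The synthetic generator

The generator is deliberately the simplest geometry for which every
downstream quantity has a closed form: femoral condyles are spheres
tangent to the joint line, the medial plateau is planar, the lateral
plateau plane can be tilted to create a frontal deformity, and shafts are
cylinders (optionally bent, for axis tests). Analytic landmarks — sphere
centers and radii, plateau planes, joint line, shaft axes — ride along with
each model so tests can compare mesh-derived quantities against closed
forms rather than against the code under test.

Defaults encode the study conditions: constant 22 mm condylar radii, 46 mm
condylar separation, a 50 mm plateau A-P depth (so the native plateau
matches the mid-sized 50 mm baseplate and standardization is the identity
for the default knee), schedules as above, 13° of internal rotation at
maximum flexion (the cohort-scale magnitude), a 5.1 mm (step up) / 4.5 mm
(chair rise) posterior shift of the medial condyle at 30° for native
screw-home paths, and zero medial shift for the TKA medial-pivot path.
The screw-home path places 70 % of the total rotation in the terminal
schedule arc (satisfying "most of the rotation in the final arc"); the
progressive path is linear in flexion. Both paths reach the same maximum
rotation, mirroring the finding structure that magnitudes match while
paths differ. The medial shift ramps linearly from extension to 30° and is
constant above — the shallowest shape consistent with a single reported
value at 30°.

Flexion is applied about the trans-condylar-center axis, so the condylar
sphere centers are motion-invariant and the imposed I-E rotation about the
tibial proximal axis is *exactly* the quantity the lowest-point pipeline
should recover; ground truth is therefore exact, not itself simulated.

Registration noise emulates single-plane fluoroscopy anisotropy:
translation noise of 0.25 mm SD in-plane (A-P, P-D) and 2.0 mm SD
out-of-plane (M-L), and rotation noise as a rotation vector with 0.5°
per-axis SD. These magnitudes are plausible defaults, fully configurable,
and are parameters of the generator — no per-frame registration precision
is claimed for any real dataset. Noise is applied per frame and per body
with a mandatory seed.

### Mesh resolution

Plateau and shaft surfaces are tessellated at about 1 mm edge length.
Condylar spheres are tessellated finer (0.3 mm target edge, an
icosphere-subdivision level derived from the target) because the package's
own accuracy contract — lowest point within 0.1 mm of closed-form sphere
tangency under arbitrary pose, with the 0.05 mm tie-centroid rule — is not
reliably met at 1 mm: the centroid of the tied vertex set on a 1 mm sphere
mesh can sit ~0.3 mm from the tangent point. At 0.3 mm the worst observed
tangency error over hundreds of random poses is below 0.09 mm. Both edge
lengths are `knee_spec()` fields.

## What the tests establish — and what they do not

The validation suite shows: noiseless trajectories are recovered to well
under 0.5° at every schedule angle for both rotation paths; with default
noise and three-repeat averaging the mean recovered rotation over 100
seeds is unbiased to better than 0.5°; the resection search agrees with an
exhaustive sweep oracle across 0–8° plateau deformities and fails loudly
at 30°; lowest points equal a brute-force vertex scan exactly; the Welch
test has nominal size; and arc bookkeeping telescopes exactly.

These are statements about the *pipeline*, under the generator's
assumptions. Real bones are not spheres and planes: cartilage, osteophytes
and segmentation error move patch boundaries; the medial condyle's
flattening near extension makes the lowest point drift posteriorly in
early flexion even when the flexion facet center is stationary — an
interpretive caveat of the lowest-point method itself, not something the
spherical generator can exhibit. Patient-level rotation curves therefore
cannot be reproduced from synthetic data, and no such reproduction is
attempted; cohort-*level* magnitudes are matched only in distributional
stand-in form by `generate_cohort()`.

## Numerical choices and degenerate inputs

* Plane/sphere fits are total/algebraic least squares; degenerate point
  sets (collinear patches, < 50-vertex condyle patches) raise classed
  geometry errors rather than returning garbage.
* Cross-section contours are chained by shared mesh-edge identity; an open
  chain (a hole at the level plane) is a geometry error unless a closed
  contour also exists at that level.
* The varus-valgus search asserts its own post-condition (imbalance within
  tolerance) on every success.
* Rotations in pose files must be orthonormal within 1e-6 with determinant
  +1; reflections are rejected by name of the offending frame.
* All stochastic stages take explicit integer seeds; identical seeds give
  bit-identical outputs (pose CSVs round-trip byte-for-byte).

## Problem sizes used in the shipped validation

The test suite runs the noiseless recovery on the default (fine-condyle)
model, the noise-bias study at 100 seeds × 3 repeats on one knee, the
Monte-Carlo power checks at 20,000 replicates per delta (100,000 in the
acceptance script), and the type-I-error study at 10,000 null simulations —
sizes chosen to give comfortable statistical margins for the stated
tolerances while keeping a full run in the order of a minute or two.

## Known limitations

* No cartilage-aware joint line, osteophyte handling, or general
  anatomical landmarking of real MR-derived bones; real data must arrive
  with condylar/plateau patches identified (the landmark sidecar format).
* The flexion-facet-center alternative to lowest-point tracking is
  documented but deliberately not implemented.
* Multi-body synthetic meshes are unions of closed bodies and may
  interpenetrate; no CSG union is attempted (all downstream operations are
  insensitive to this).
* The 3-D-model-to-2-D-image registration itself is out of scope; poses
  are inputs.
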