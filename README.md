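# kneetrack

Geometric analysis of in vivo tibiofemoral kinematics from surface meshes
and rigid-body pose sequences.

Single-plane fluoroscopy studies of knee function register 3-D bone or
implant models to 2-D images, producing a rigid pose of the femur and tibia
per frame. `kneetrack` implements the downstream geometry and statistics for
such studies, comparing native knees with kinematically aligned total knee
arthroplasty (KA TKA) knees that use a ball-in-socket medially conforming,
flat-lateral insert:

* **Anatomic frames.** Anatomic axes as lines through cross-section
  midpoints (7/12 cm above the joint line for the femur, 5/12 cm below for
  the tibia); flexion as the included angle between them; the femoral
  sagittal plane from the posterior condylar sphere centers.
* **Simulated tibial resection.** A plane parallel to the medial tibial
  articular surface, 10 mm distal to the medial condyle center, with its
  varus-valgus angle adjusted in 2° increments until the medial and lateral
  condylar thicknesses agree within ±0.5 mm. The tibial coordinate system
  originates at the bounding-box center of the resection contour.
* **Lowest-point condylar tracking.** The A-P position of each femoral
  condyle is the point of the condylar surface closest to the tibial
  resection plane (native) or the baseplate plane (TKA), expressed in the
  tibial frame, positive anterior; three-repeat averaging for bone-model
  registration; standardization of A-P positions to the 50 mm reference
  baseplate depth.
* **Rotation profiles.** Internal–external tibial rotation between flexion
  angles f and g as the angle between the medial–lateral lines through the
  (non-standardized) condylar positions,
  θ(f) = atan2(AP_med − AP_lat, ML_lat − ML_med), reported relative to full
  extension, with per-arc changes (15° arcs for step up, 30° for chair
  rise).
* **Cohort statistics.** Welch (default) or pooled two-sample comparisons
  at maximum flexion and per arc, Pearson chi-square for categorical
  variables, and a noncentral-t power analysis: with n = 25 per group,
  α = 0.05 and group SDs of 2.9° and 4.6°, the minimum detectable rotation
  difference at 80 % power.
* **Synthetic data.** A parametric knee/TKA generator (spherical condyles,
  planar plateau — every downstream quantity has a closed form), ground-truth
  trajectories with screw-home or progressive (medial-pivot) rotation paths,
  and an anisotropic registration-noise model, so the whole pipeline is
  testable without patient data.

## Worked example

Generate a native knee performing a step up with a screw-home rotation
path (13° of internal rotation at 60° flexion, most of it in the final arc
of extension), then recover the kinematics from the meshes and poses alone:

```r
library(kneetrack)

model  <- generate_knee_model(knee_spec())
motion <- motion_spec("step_up", rotation_path = "screw_home",
                      max_internal_rotation = 13)
traj   <- generate_trajectory(model, motion)

res <- analyze_knee(model, traj$poses, activity = "step_up")
res$profile
#> <rotation_profile> step_up, rotation at maximum flexion 13.00 deg
#>  flexion_deg rotation_deg
#>           60         13.0
#>           45         11.7
#>           30         10.4
#>           15          9.1
#>            0          0.0
#> arcs of extension:
#>    arc flex_from flex_to delta_deg
#>  60-45        60      45       1.3
#>  45-30        45      30       1.3
#>  30-15        30      15       1.3
#>   15-0        15       0       9.1
```

The profile recovers the imposed path: 13.0° at maximum flexion and 9.1°
(70 % of the total) in the terminal 15°→0° arc — the screw-home signature.
The condylar track shows the 5.1 mm posterior shift of the medial condyle
at 30° that the native-knee generator imposes:

```r
round(res$track, 2)
#>   flexion_deg ap_med ml_med ap_lat ml_lat
#> 1          60  -5.09 -22.41 -15.44  22.41
#> 2          45  -5.11 -22.52 -14.44  22.52
#> 3          30  -5.16 -22.63 -13.46  22.61
#> 4          15  -2.53 -22.71  -9.81  22.71
#> 5           0   0.00 -23.00   0.00  23.00
```

The power analysis for the two-group design:

```r
power_at(2.8, power_spec())          # power at a true 2.8 deg difference
#> [1] 0.8122665
detectable_difference(power_spec())  # minimum detectable difference (deg)
#> [1] 2.750584
```

A thin command-line wrapper over the same functions lives at
`inst/cli/kneetrack.R` (subcommands `simulate`, `analyze`, `stats`,
`power`).

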