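# boxkin

Upper-limb kinematics for boxing-style motion capture: a constrained
multibody model, weighted multibody kinematic optimization (MKO), kinematic
variable extraction, and a Bland–Altman method-agreement battery — with a
synthetic-data generator so the whole chain is testable end to end without
laboratory data.

## The problem

Markerless (video-based) motion capture is attractive for "in the field"
sports analysis, but its accuracy for the upper limb in highly dynamic
movements — punches reach hand speeds above 7 m/s — has to be quantified
against the marker-based standard. Doing that comparison requires a full
computational chain:

1. **A constrained upper-extremity multibody model.** The thorax is the
   root segment with 6 degrees of freedom (DoF); each side chains a
   clavicle (2 rotational DoF), upper arm (3-DoF ball shoulder), forearm
   (2-DoF elbow, abduction/adduction locked) and hand (2-DoF wrist,
   internal/external rotation locked): 24 generalized coordinates `q` in
   total. Segment lengths and centers of mass come from a sex-specific
   anthropometric table scaled by stature; elbow and wrist joint centers
   are epicondyle/styloid midpoints.
2. **Multibody kinematic optimization.** Per frame, the chain is fitted to
   labeled marker positions by bounded Levenberg–Marquardt least squares

   `min_q  Σ_i w_i ‖m_i − m̂_i(q)‖²`

   with segment-specific marker weights ordered thorax > upper arm >
   forearm > hand, an analytic geometric Jacobian, and locked DoFs excluded
   from `q` (constraints hold exactly by construction).
3. **Kinematic variables.** Joint angles by intrinsic Z-X-Y cardan
   decomposition (flexion/extension, abduction/adduction, internal/external
   rotation), 3D joint-center distances between two pose streams, and
   segment center-of-mass speed magnitudes; all comparison series pass a
   zero-phase 4th-order low-pass Butterworth filter (8 Hz cutoff) at the
   common 60 Hz comparison rate.
4. **Agreement statistics.** For each variable, pooled differences
   `d = test − reference` give the Bland–Altman bias `b` and confidence
   interval `CI` (`1.96·sd(d)` under normality, `1.45·IQR(d)` otherwise,
   Shapiro–Wilk at α = 0.05), plus `R²` (squared Pearson correlation) and
   `RMSD`; joint-center distances are summarized as median (IQR) in cm.

Because real athlete recordings are typically not shareable, the package
ships a **synthetic trial generator**: minimum-jerk punch trajectories
calibrated to a target peak hand speed, footwork and postural sway,
soft-tissue-artifact/jitter/placement marker corruption, and an emulated
60 Hz markerless pose stream with injectable angle biases and joint-center
offsets — so every downstream stage can be validated against known ground
truth.

## Worked example

```r
library(boxkin)

chain <- build_chain(anthro_profile("male", 1.90, 78))
chain
#> <kinematic_chain> 9 segments, 9 joints, n_q = 24, 21 markers
#>   profile: male, 1.90 m, 78.0 kg

# a lead-arm direct-punch trial, peak hand speed calibrated to 7.5 m/s
script <- punch_script("direct_face", repetitions = 4, peak_hand_speed = 7.5)
sim <- simulate_trial(chain, script,
                      corruption = corruption_model(placement_offset_sd = 0),
                      emulation = system_emulation(
                        angle_bias = c(shoulder_L.flex_ext = 2.4 * pi / 180),
                        center_offset = list(elbow_L = c(0.0179, 0.0179, 0.0179))),
                      seed = 1)

sol <- solve_trajectory(chain, sim$markers)        # MKO, ~11 ms/frame
ref <- export_poses(chain, sol$q_traj)             # 300 Hz pose stream
cmp <- compare_streams(ref, sim$markerless, chain) # align at 60 Hz + filter
rep <- build_report(cmp$angles_ref, cmp$angles_test,
                    cmp$speeds_ref, cmp$speeds_test, cmp$distances)

subset(as.data.frame(rep$angles),
       joint == "shoulder" & side == "front" & axis == "flex_ext")
#>      joint  side     axis        b       ci        r2     rmsd   n normal
#> 1 shoulder front flex_ext 2.647848 2.517026 0.9912574 3.058406 337  FALSE

as.data.frame(rep$joint_centers)[3, ]
#>   joint  side median_cm    iqr_cm   n
#> 3 elbow front  3.162006 0.3842467 337
```

The recovered shoulder flexion/extension bias (2.65°) matches the injected
inter-system bias (2.4°) within the soft-tissue-artifact noise floor, and
the median lead-elbow center distance (3.16 cm) recovers the injected
3.1 cm offset — the two headline quantities a method-comparison study
reports. `run_study()` wraps the whole chain behind one YAML-configurable
call, and `inst/cli/boxkin.R` exposes `simulate | solve | compare | report
| run-all` subcommands for shell use.

## Scope

The package models the upper extremity only (no lower limbs, head,
scapulo-thoracic rhythm or inertia) and emulates — rather than implements —
the video side of a markerless system: no camera calibration, 2D keypoint
detection or triangulation. See the methods vignette
(`vignettes/boxkin-methods.Rmd`) for the model conventions, parameter
choices, and known limitations.
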