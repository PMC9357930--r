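---
title: "Models and methods behind boxkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind boxkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(boxkin)
```

boxkin compares two ways of measuring upper-limb kinematics during
punch-like movement: a marker-based chain (labeled 3D markers fitted by
multibody kinematic optimization) and a markerless-style stream of
per-segment pose matrices. This vignette documents the model, the numerical
choices, and what the synthetic validation does and does not establish.

## The multibody model

The chain has nine segments: a thorax root with three free translations and
three free rotations, and per side a clavicle, upper arm, forearm and hand.
Joint constraints are expressed in minimal coordinates — a locked degree of
freedom simply does not exist in the parameter vector `q` (length 24), so
constraints are satisfied exactly rather than penalized:

* sternoclavicular: 2 DoF — elevation/depression and
  protraction/retraction. With the clavicle's long axis pointing laterally,
  these are the two rotations that actually displace the shoulder; a
  rotation about the clavicle's own long axis is nearly unobservable from
  surface markers and is therefore the locked one.
* shoulder: 3 DoF ball joint;
* elbow: 2 DoF, abduction/adduction locked;
* wrist: 2 DoF, internal/external rotation locked.

**Frames and conventions.** The global frame is X anterior, Y vertical up,
Z to the subject's right. Every template segment rotation is the identity
in the neutral standing posture, so the geometry lives entirely in the
joint offset vectors and relative joint rotations decompose exactly into
the joint's cardan angles. Angles use the intrinsic Z-X-Y sequence —
flexion/extension about Z, abduction/adduction about X, internal/external
rotation about Y — for every joint alike, because the agreement tables
report all three joints on those axes (a Y-X-Y shoulder sequence could
not). The sequence is configurable per call. Reported angles follow the
convention flexion/abduction/internal positive on both sides, which
mirrors the raw abduction and internal-rotation signs between left and
right.

**Anthropometry.** Segment lengths are sex-specific fractions of stature
and centers of mass fractions of segment length, shipped as an editable
table (`inst/extdata/anthro.csv`) with representative values in the spirit
of the usual regression sources. No test depends on these constants: the
generator and the solver share one chain object, so the validation is of
the computational chain, not of the anthropometric table. `scale_template()`
adapts the generic template to a subject by ratio-scaling each segment
against an inter-landmark distance measured in a static frame, then
re-derives marker local positions from one static MKO fit; a static frame
rendered from the chain itself is a fixed point of this operation.

**Joint centers.** The model defines elbow and wrist centers as
epicondyle/styloid midpoints and shoulder/spine centers as stored local
points in the proximal segment frame (`joint_centers()`). For comparing two
pose streams, `joint_center_distance()` instead reads each center as the
origin of the joint's distal segment frame — the natural reading of
per-segment pose exports, and identical to the proximal definition whenever
the stream is chain-consistent (as every MKO output is).

## Multibody kinematic optimization

Each frame minimizes the weighted sum of squared marker residuals over the
free coordinates, with bounds (±π on angles, elbow flexion restricted to
[0°, 160°] to exclude mirror solutions, ±10 m on the root translation)
under Levenberg–Marquardt trust-region least squares (`minpack.lm`),
tolerances 1e-15 (objective) and 1e-12 (step), at most 200 iterations per
frame. Default marker weights are 10 (thorax), 5 (clavicle/upper arm),
2 (forearm), 1 (hand); the ordering reflects decreasing skin-marker
fidelity toward the distal end, the magnitudes are free and can be selected
by residual analysis (`tune_weights()`, which scores candidates by
weight-normalized residual RMS so rescaling a scheme does not change its
score; ties go to the first candidate).

Two numerical choices matter in fast punching motion:

* **Analytic geometric Jacobian.** The derivative of a marker position with
  respect to a rotational coordinate is `axis × (p − center)` with the
  cardan axis directions evaluated at the current configuration. Near full
  arm extension the shoulder and elbow internal-rotation axes align and the
  objective develops nearly flat valleys; forward-difference derivatives
  drown in round-off exactly there, stalling the solver, while the analytic
  Jacobian keeps gradients exact near zero residual.
* **Warm-start regularization.** Frame *k* starts from the linear
  extrapolation of the two previous solutions, and a tiny ridge (1e-9 in
  weighted-residual units) toward that start selects the
  continuity-preserving solution along flat directions; an unregularized
  polish pass then removes the (already negligible) ridge bias, so
  noise-free data are recovered to machine precision. Frames with fewer
  than three usable non-collinear markers are flagged invalid and never
  interpolated.

On noise-free synthetic trials the solver recovers the generating
coordinates to ~1e-15 rad at roughly 11 ms/frame; on the planar two-link
reduction it matches closed-form inverse kinematics to 1e-9 rad.

## The synthetic study

The generator emulates a shadow-boxing session: repetitions of a punch
combination (direct to face/body, double direct, rear jab + lead hook,
uppercut-hook-hook) separated by guard holds with footwork.

* **Punch shape.** Minimum-jerk interpolation between guard and extended
  target postures — C², with zero end velocities and a closed-form peak
  rate factor (1.875·Δ/T). Extension takes 35% of the punch duration
  (an elite jab extends in roughly 100–150 ms), retraction 65%.
* **Peak-speed calibration.** Punch amplitudes are scaled by secant
  iteration until the measured peak hand center-of-mass speed matches the
  script's target within 0.5% (the default target, 7.5 m/s, is a typical
  elite lead-hand peak). Amplitudes are capped by the coordinate bounds; an
  unreachable target raises an error stating the attainable bound.
* **Footwork and postural sway.** The root oscillates at ~0.3–0.5 m/s peak
  (within the 0–1.5 m/s range seen between punches), and every free joint
  angle receives a slow 1–1.5° oscillation — no human holds a joint
  perfectly still, and perfectly constant series would make correlation
  statistics degenerate. Sway amplitudes shrink automatically near
  coordinate bounds.
* **Marker corruption.** Three seeded terms: a constant per-marker
  placement offset (isotropic Gaussian, default sd 5 mm), a band-limited
  soft-tissue-artifact displacement (Gaussian noise low-passed at 3 Hz and
  rescaled to a 3D RMS of 10 mm on the arms, 5 mm on the thorax), and white
  jitter (0.5 mm). The magnitudes are order-of-magnitude stand-ins for
  skin-marker error, reported in metadata, not asserted as a validated
  soft-tissue model.
* **Markerless emulation.** The ground-truth coordinates are resampled to
  60 Hz; constant angle biases and Gaussian pose noise are injected in
  coordinate space (so every output pose is exactly rigid); forward
  kinematics produces the stream. Segment origins stay anchored to the
  unbiased kinematics: a markerless system estimates positions from image
  evidence, so an orientation offset should not proportionally displace its
  joint centers. Explicit per-joint center offsets then displace the
  corresponding distal-segment origin directly. This decoupling is what
  makes "inject a 5° shoulder bias and a 3 cm elbow offset, recover both"
  a well-posed calibration scenario.

**Calibration scenarios exclude placement offsets.** A constant placement
offset induces a systematic marker-side angle offset that is
indistinguishable from the inter-system bias being recovered; the bundled
default scenario therefore sets `placement_offset_sd = 0` while keeping
the dynamic (zero-mean) corruption terms. The general corruption default
keeps 5 mm placement noise.

## Filtering and comparison

Joint angles and segment speeds are extracted first and filtered after
(4th-order low-pass Butterworth, 8 Hz cutoff, forward-backward). The
forward-backward pass is started in steady state for the signal's first
value and preceded by odd-reflection padding of at least three filter time
constants, giving unit DC gain to round-off and zero phase; no
cutoff-frequency correction is applied for the dual pass, so the documented
contract is −6 dB (amplitude 0.5) at 8 Hz. `NA` gaps are preserved and
finite runs filtered piecewise; runs shorter than the padding are left
unfiltered with a warning.

All agreement statistics are computed at 60 Hz: the 300 Hz marker-derived
series are anti-alias filtered (zero-phase Butterworth at 45% of the target
rate) and interpolated onto the 60 Hz timestamps, because the lower-rate
stream cannot be upsampled without inventing data. Pose matrices themselves
are decimated onto the shared grid (rotations cannot be linearly
interpolated); for the smooth motions involved the difference is
negligible.

Peak segment speeds are read off the native-rate solved stream under a
light 20 Hz low-pass: well above punch signal content, so the pulse is not
attenuated, but enough to suppress differentiated marker jitter that
would otherwise inflate maxima. The 8 Hz agreement filter is deliberately
not used for peak extraction — the fastest calibrated extensions
(~0.14 s) have spectral content near 8 Hz, where the agreement filter
attenuates peaks by design.

## Agreement battery

For each variable the differences are pooled across trials and sides
before statistics. Normality is assessed by Shapiro–Wilk at α = 0.05
(deterministically subsampled to 5000 points when larger); the normal
branch reports mean and 1.96·sd, the robust branch median and 1.45·IQR
(linear-interpolation quantiles, type 7 — fixed because the IQR enters the
CI formula). `R²` is the squared Pearson correlation between the two
methods' series: the customary association companion to Bland–Altman, with
the documented blind spot that a pure constant offset still yields
`R² = 1` (which is exactly why it is paired with the bias). `RMSD` is the
root mean square difference; on the normal branch
`RMSD² = b² + var(d)·(n−1)/n` holds as an algebraic identity. Variables
whose model axis is locked (elbow abduction/adduction, wrist
internal/external rotation) are absent from the report tables.

## Problem sizes used in validation

The bundled default study is one trial of four lead-arm direct punches
(~5.6 s at 300 Hz, ~1700 frames solved by MKO, compared over ~340 pooled
60 Hz frames). The end-to-end acceptance scenario uses the same shape with
a 5° shoulder bias and 3 cm elbow offset; the noise-monotonicity check
solves a 40-frame punch window under 20 jitter replicates at each of
0/1/2/5 mm. These sizes were chosen to exercise every stage at full
fidelity while keeping a complete validation run in the minutes range on
one CPU.

## What passing tests do and do not show

The synthetic validation establishes that the chain is self-consistent:
the solver inverts the forward model exactly, injected inter-system biases
and center offsets are recovered within the soft-tissue noise floor, and
the statistics reproduce their defining formulas. It does not establish
accuracy on real athletes: the soft-tissue model is a band-limited
stand-in, the markerless emulation bypasses the entire video pipeline
(calibration, keypoint detection, triangulation), segment frame-definition
discrepancies between real systems are reduced to injectable offsets, and
the generator's punches — however calibrated in peak speed — are smoother
than real inter-segmental coordination. Known limitations: no
scapulo-thoracic rhythm (clavicle motion folds into the reported shoulder
angle), no lower body (peak speeds above ~7 m/s require unrealistically
fast arm extension because the legs' contribution is absent), and
internal/external rotation is intrinsically poorly conditioned near full
arm extension — visible in the wider dispersion of that axis in any
agreement table this package produces.
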