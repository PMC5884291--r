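---
title: "Methods: trajectory cleaning, joint kinematics, and method validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory cleaning, joint kinematics, and method validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinagree)
```

`kinagree` turns depth-sensor skeleton recordings of upper-limb movement
into clinical joint angles and validates that measurement chain against
manual goniometry. This vignette is the package's account of the methods:
the models, the parameters that matter, the numerical choices, and what the
synthetic experiments do and do not demonstrate.

## Coordinate conventions

All positions are in metres in the camera frame — x to the camera's right,
y up, z away from the sensor along the depth axis — time in seconds, angles
in degrees. These units are fixed, not configurable: a single-unit
discipline removes a whole class of silent errors in clinical code.

Anatomical planes are axis-drop projections of the camera frame: coronal
keeps (x, y), sagittal keeps (y, z), axial keeps (x, z). This identifies
the subject's anatomical planes with the camera planes, which is exact only
for a subject squarely facing the sensor — the intended acquisition posture
(2 m distance, facing the device).

The skeleton carries the standard 20-joint standing registry or a 10-joint
seated registry (head, shoulder centre, and shoulder/elbow/wrist/hand per
side). Body segments chain anatomically: trunk (hip centre → shoulder
centre), shoulder line (shoulder centre → shoulder), arm (shoulder →
elbow), forearm (elbow → wrist), hand (wrist → hand). The segment endpoint
pairs are a documented modelling choice — the only chain consistent with
naming the segments trunk, shoulders, arm, forearm and hand. Because the
seated registry has no hip centre, the trunk segment (and with it the
trunk-referenced shoulder angles) is available from standing recordings
only.

## Trajectory cleaning

Depth-sensor joint estimates fail in isolated frames — typically when
joints overlap along the depth axis and the tracker can only guess.
Cleaning runs in three fixed stages per joint per coordinate, in pipeline
order; every stage preserves series length, and the per-stage intermediates
are retained for plotting.

### Stage 1: local outlier replacement

Sample $x_i$ is flagged when it leaves the band
$[\bar x - 1.96\,\sigma,\ \bar x + 1.96\,\sigma]$ computed over a local
window, and replaced by the mean of its two neighbours. The first and last
samples have no two-sided neighbourhood and are never replaced. Thresholds
and replacements are computed from the original input in one pass, so the
result does not depend on scan order.

The choice of window deserves care. If $\bar x$ and $\sigma$ are taken over
the full three-point window *including the candidate* (population
$\sigma$), the rule is provably inert: for any three numbers the largest
attainable $|x_i - \bar x| / \sigma$ is $2/\sqrt{3} \approx 1.155$, below
the 1.96 threshold, so nothing can ever be flagged. The package therefore
defaults to computing $\bar x, \sigma$ over the two *neighbours* only — the
only local variant that both detects spikes and is consistent with
replacing the flagged value by the neighbours' mean. The inert
`"literal3"` variant and a whole-series `"global"` variant remain
selectable for transparency, and the policy in force is recorded in
outputs. Population (divide-by-count) $\sigma$ is used wherever a window of
at most three points is involved.

One behaviour of the neighbours rule is worth knowing: at a smooth
extremum of a noiseless curve the symmetric spread
$|x_{i+1} - x_{i-1}|/2$ vanishes while the centre deviates by curvature, so
turning points of clean trajectories can be flagged. The replacement error
there is second-order (about $L\,\Delta\theta^2/2$, ~$10^{-4}$ m at typical
frame rates) and clinically irrelevant, but flag counts on clean data need
not be exactly zero.

### Stage 2: block interpolation

The series is partitioned into consecutive non-overlapping blocks of 10
samples; within each complete block the 8 interior values are replaced by
the straight line joining the block's first and last values. A trailing
partial block has no endpoint pair to interpolate between and passes
through unchanged. The stage is a projection (applying it twice changes
nothing) and leaves any locally-linear trajectory untouched; on curved
trajectories it introduces a chord-versus-arc deviation of roughly
$r\,\Delta\theta_{\text{block}}^2/8$ — about 5 mm at the hand for a
45°/s sweep at 30 fps — which is the dominant distortion of the whole
pipeline and the reason the end-to-end angle error budget below is a few
tenths of a degree rather than zero.

### Stage 3: moving average

Each output sample is the mean of a centred window of up to `window_n`
input samples, $\bar x = \sum_i x_i / n$. The window length is a free
parameter; the default is 5 frames (0.17 s at 30 fps), odd so the filter is
phase-neutral and short enough not to distort movement at rehabilitation
speeds. At the edges the window is clipped to the available samples (the
variant matching the package's windowed-mean definition exactly); on a
trending signal this biases the first and last couple of frames toward the
interior — visible as ~2 cm at the hand for fast sweeps — so edge frames of
very short recordings deserve suspicion regardless of smoothing choice.

## Joint angles

Angles use the classical included-angle formula between two segment
vectors,
$$\Theta = \cos^{-1}\!\left(\frac{P_1 \cdot P_2}{\lVert P_1\rVert\,\lVert P_2\rVert}\right),$$
evaluated per frame, in degrees in [0, 180]. The normalised inner product
is clamped to $[-1, 1]$ before `acos` so parallel vectors whose product
rounds to $1 + \varepsilon$ never yield `NaN`. Vectors with norm below
$10^{-9}$ m mark the frame missing (`NA`) rather than inventing an angle:
filling degenerate frames would fabricate clinical data. Note the
conditioning of `acos` degrades near 0° and 180°, where position noise of
fixed size produces the largest angle perturbations.

Clinical angles are defined in an articulation registry as reference/segment
vector pairs. Shoulder abduction and flexion measure the arm against the
trunk-down direction (shoulder centre → hip centre), so a hanging arm reads
0°; elbow and wrist angles are the included angle between adjacent
segments, 0° = straight. Plane-projected angles project both vectors before
the formula. The registry is the single place these conventions live and is
deliberately easy to extend.

For the axial-plane movement variant the trunk-down reference is normal to
the axial plane, so its projection vanishes and a projected axial angle is
degenerate by construction; axial movements are therefore evaluated with
the 3D angle (the arm's elevation stays at 90° while its azimuth sweeps).

Trajectory summaries report range of motion (max − min of the angle
series), path length (summed distance between consecutive end-effector
positions) and covered area. No standard definition of covered area exists
for this display; the package uses the convex-hull area of the projected
end-effector path — deterministic and parameter-free — noting that a
triangle-fan from the shoulder pivot is a reasonable alternative for
strongly non-convex paths. Degenerate paths (fewer than three distinct
points, collinear) give area 0 with a warning, not an error.

## Agreement and repeatability

Two instruments measuring the same angle are compared by *agreement*, not
correlation: when neither instrument is the truth, the clinically relevant
question is how far apart their readings can be. For paired readings the
per-pair difference $d = a - b$ and mean $m = (a+b)/2$ give the
Bland-Altman plot; the bias is $\bar d$ and the 95% limits of agreement are
$$\bar d \pm 1.96\,\mathrm{sd}(d).$$
The limits are centred on the mean *difference* — with small $n$, sample
(n−1) standard deviations — and points exactly on a limit count as within.
The difference direction (first argument minus second) is fixed and echoed
in every report.

Repeatability uses the same construction on two sessions of the same
instrument, $u = s_1 - s_2$, limits $\bar u \pm 1.96\,\mathrm{sd}(u)$,
plus the coefficient of repeatability
$$CR = \sqrt{\tfrac{1}{n}\sum u^2},$$
the bound below which about 95% of repeat differences are expected when
$\bar u \approx 0$ (the British Standards reading). The identity
$CR^2 = \sigma_u^2 + \bar u^2$ (population variance) makes CR's relation to
the limits explicit. `cr_percent` divides CR by a stated reference angle —
the protocol's nominal 90° by default, never a hidden constant — because a
"percent variation" without its denominator is meaningless.

## The synthetic experiments

The simulator exists so that every statistical claim above can be exercised
with known ground truth. It emulates:

* **Movement** — a rigid two-segment-plus-hand arm on a fixed trunk,
  shoulder pivot, straight elbow, driven by a commanded angle-versus-time
  profile in one plane, sampled at 30 fps. Segment lengths scale from
  stature (default 1.69 m, the validation cohort's mean) with standard
  anthropometric fractions. An arm hanging at the side is 0°; the subject
  faces the sensor at 2 m, so the right arm appears at negative camera x.
* **Sensor noise** — isotropic Gaussian position noise on every joint
  coordinate. The default sd of 0.0245 m sits midway in the device's
  reported 14.1–34.8 mm error range. Isolated outliers displace a joint by
  `outlier_scale` × sd in a random direction with probability
  `outlier_rate` per joint-frame (default 1%, an exercise setting — the
  true device outlier frequency is not reported anywhere we know of).
* **The goniometrist** — reading = truth + observer bias + Gaussian
  observer noise (default sd 1°, a typical intra-observer figure), rounded
  to whole degrees (instrument resolution).

Protocol 1 (agreement) has each subject hold every 10° step from 0° to
180° of coronal abduction with both arms while the angle is read by the
goniometer model and by the full pipeline — a 1 s static burst, cleaned,
converted to a coronal angle series, median-aggregated (median over 30
frames, robust to residual outliers). Nine subjects give the 342 pairs of
the emulated study design. Protocol 2 (repeatability) repeats a 90°
flexion in two sessions per subject, adding session-level Gaussian
variation (set-up, posture, lighting differences between visits); its
default sd, 3.204/√2 degrees per session, is calibrated so the session
difference has sd 3.204° and the repeatability interval is about ±6.28°.

What the simulator does *not* model: soft-tissue and tracker-model bias
(systematic, posture-dependent joint mis-placement), occlusion, autocorrelated
noise, elbow flexion during "straight-arm" tasks, or inter-subject
anthropometric variation beyond overall stature. Passing the synthetic
experiments therefore demonstrates that the *statistics and the pipeline*
behave as designed under the stated noise model — it does not certify any
particular hardware accuracy on real patients.

Two noise-model consequences are worth internalising. First, single-frame
angle noise follows the small-angle propagation
$\sigma_\theta \approx \sqrt{2}\,\sigma_{\text{pos}} / L$ for a segment of
length $L$ (both endpoints noisy): ~2.7° for a 0.60 m shoulder-to-wrist at
$\sigma_{\text{pos}}$ = 20 mm — before smoothing and median aggregation cut
it several-fold. Second, near 0° and 180° the recovered angle is clamped to
[0, 180], so noisy estimates at the range ends are biased inward; on the
symmetric 0–180° grid of Protocol 1 these edge biases cancel in the mean,
which is why the injected observer bias is recovered without correction.

## Problem sizes and numerical notes

The shipped experiments use: 10,032 pairs (264 synthetic subjects) for the
Bland-Altman coverage calibration, 10,000 session differences for the
2-sd repeatability convention, 20 replicates of the 342-pair protocol for
bias recovery, 1,000 subjects for the repeatability-limit recovery, and a
6 s / 180-frame ramp for end-to-end fidelity — sizes chosen so Monte-Carlo
error is a fraction of each quantity's tolerance while a full run stays in
the minutes range on a single core.

Numerical choices, collected: `acos` arguments clamped to [−1, 1];
degeneracy threshold $10^{-9}$ m on vector norms; moving average via
cumulative sums (agreeing with naive summation to ~$10^{-13}$, with
constant series short-circuited exactly); all seeds explicit, every
generated artefact carrying its full configuration; protocol generators
ignore a seed embedded in the noise configuration so that consecutive
bursts draw fresh noise from the protocol-level stream.

## Known limitations

Beyond the simulator gaps above: the cleaning pipeline assumes a regular
frame clock (no gap-filling or resampling); the neighbours-only outlier
rule can clip sharp genuine direction reversals in very fast movements; the
convex-hull covered area over-reports concave paths; plane-projected angles
are meaningful only for a subject square to the camera; and the block
interpolation stage, kept for fidelity to the original processing design,
is the pipeline's main source of systematic trajectory distortion — setting
a larger smoothing window and skipping interpolation would be the natural
variant for new protocol designs.
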