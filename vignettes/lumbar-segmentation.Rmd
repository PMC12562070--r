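---
title: "Comparing lumbar marker-set models in the sagittal plane"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing lumbar marker-set models in the sagittal plane}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the measurement model

Optical motion capture tracks reflective markers on the skin over the
spinous processes. Whether two markers (a single rigid lumbar segment),
three (two segments) or five (every lumbar vertebra) are needed depends on
how much the torso's shape changes during the movement of interest. This
package operationalizes that comparison for sagittal-plane
flexion–extension exercises.

For each analyzed posture ("capture"), spine markers are projected into the
sagittal plane of a pelvis anatomical frame. The frame is built per video
frame from the pelvis markers: the mediolateral (ML) axis along the line
through the left and right PSIS/ASIS side midpoints, the anteroposterior
(AP) axis as the ASIS-midpoint minus PSIS-midpoint direction
orthogonalized against ML, and the longitudinal axis as AP × ML
(right-handed; determinant +1 by construction). Projection yields
coordinates $u$ (longitudinal, cranial positive) and $v$ (AP, anterior
positive), both relative to the pelvis origin, so the whole analysis is
pelvis-relative and invariant to rigid motion of the subject in the lab.

Each marker-set model $m$ fits a polynomial $v_m(u)$ by least squares —
degree 1 for the two-marker models (1: L1/L5; 2: T10/S1), degree 2 for the
multi-marker ones (3: L1/L3/L5; 4: L1..L5); with point count = degree + 1
the fit interpolates exactly. All models are evaluated at five equidistant
$u$ values over the capture's lumbar span $[u(\mathrm{L5}),
u(\mathrm{L1})]$. Evaluating Model 2's T10–S1 line restricted to that same
span is a deliberate choice: pointwise comparison of curves is only
meaningful on a common abscissa (a per-model span is available via
`default_config(shared_eval_range = FALSE)`). Agreement between models $i$
and $j$ is the sample Pearson correlation $r$ of the two 5-vectors of
ordinates, computed per capture and aggregated per exercise/phase cell as
mean ± SD over captures. A pooled correlation over all captures' points was
rejected because it cannot produce a per-cell SD and would mix
between-capture variance into the agreement measure. If a model's five
ordinates are (numerically) constant, $r$ is undefined; such captures are
excluded and logged, never imputed, since a horizontal line carries no
shape information to correlate.

Note a structural property worth knowing when reading reports: two
first-degree models always correlate at exactly ±1 (five collinear points),
so cells for the 1-vs-2 pair show means like 0.53 ± 0.85 when the two
lines' slopes disagree in sign for part of the cohort — near the mid-cycle,
where the spine's chord is nearly parallel to the pelvis longitudinal axis,
the slope sign is numerically delicate. That is a property of comparing
lines by correlation, not an artifact.

Lumbar curvature is quantified once per capture, independently of the
models, by the circle-fit method: a circle is fitted to the five lumbar
markers and the lordosis angle is the central angle between the radii
through L1 and L5. The fit is Taubin's algebraic circle fit, which
minimizes an approximation of geometric distance, has no iterative
initialization worries (a Newton polish from η = 0 suffices; exact data has
its root at 0) and reduces to the circumcircle for three points. Sign
convention: positive when the curve is posteriorly convex (flexed,
kyphotic; circle center anterior of the L1–L5 chord), negative when
lordotic. The convention makes relative lordosis increase with flexion,
matching how the exercise extremes order themselves. Markers collinear
within tolerance (`collinear_tol_mm`, default 1e-6 mm maximum perpendicular
deviation) yield a "straight spine" result with angle 0 by continuity,
reported distinctly from failure. Relative lumbar lordosis is the capture's
angle minus the participant's standing reference, taken as the mean over
their four STA captures (a single-capture reference would inject one
capture's noise into every other number of that participant).

## Processing chain and its parameters

All tunables live in `default_config()`:

* `cutoff_hz = 5`, `filter_order = 4` — fourth-order low-pass Butterworth,
  applied forward–backward (zero-phase) per marker per axis so event timing
  is not lagged. The net gain at the cutoff is therefore 0.5. The
  implementation detrends between the endpoint samples and pads by odd
  reflection before filtering, so constant trajectories pass through
  bit-near-identically and startup transients never reach the kept samples.
* `max_gap_frames = 24` (0.2 s) — interior gaps up to this length are
  filled per axis by a local cubic spline. Longer or boundary gaps of
  lumbar markers are rebuilt from the lateral markers: the target is the
  bracketing lateral pair's midpoint plus a constant offset learned by
  least squares in a donor frame (pair ML line + direction to the other
  pair's midpoint) over the frames where target and donors coexist. The
  construction is exactly rigid under rigid motion. Anything left unfilled
  is reported, never silently interpolated.
* `n_cycles_extracted = 4`, `phase_percents = c(0, 25, 50, 75, 100)` — the
  torso angle (signed angle between the projected C7→S1 line and the
  pelvis longitudinal axis; extension positive, flexion negative) drives
  cycle detection. Alternating extrema are found with a prominence
  threshold (`prominence_frac = 0.25` of the series' peak-to-peak range —
  robust to filtered noise without assuming any absolute amplitude), and
  of the five performed cycles the first is dropped as familiarization,
  keeping cycles 2–5. Each kept cycle splits at its flexion extreme into a
  flexion half (max extension → max flexion) and an extension half, each
  sampled at the phase percentages by nearest-frame rounding (ties round
  down, for determinism).
* Extremum localization: slow movement cycles are flat near their extrema,
  so the raw argmax under noise wanders by several frames. Each raw
  extremum is refined to the vertex of a quadratic fitted over 0.4× the
  inter-extremum gap on an event-band moving-average copy of the series
  (window 0.2× the median inter-extremum gap). Both operations are
  symmetric, so noiseless extrema do not move; under 2 mm marker noise the
  localization error is typically ≤ 1 frame (99th percentile 2 frames in a
  48-trial ensemble), with rare ~5-frame cases on the flattest
  (low-amplitude) trials.
* `n_static_captures = 4`, `steady_tol_deg = 2` — static holds are located
  as the longest span where the torso angle stays within ±2° of its
  median; captures sit at the centers of the window's four equal
  subdivisions. Center sampling matters: the rise/fall transients of the
  prone exercises converge smoothly into any tolerance band, and
  endpoint sampling would capture transient frames.

## The synthetic cohort

No public recordings exist for this kind of protocol, so the generator is a
first-class, tested module, and its defaults are the study conditions the
analysis assumes: 17 participants (6 male / 11 female; heights drawn from
178.5 ± 8.1 cm and 160.3 ± 6.6 cm respectively), six exercises, 120 Hz,
2 mm i.i.d. Gaussian soft-tissue noise per axis (configurable up to the
~15 mm worst cases reported for lumbar skin markers), occlusion gaps
starting at 0.01 per marker-second, 5–20 frames long.

Kinematics: the lumbar markers L1..L5 lie exactly on a circular arc whose
L1–L5 central angle is the commanded curvature; S1 continues the arc one
angular step (a quarter of the L1–L5 angle) below L5; chain arc length is
0.16× body height, split equally. The thoracic chain is a single straight
segment from L1 (T10 at 0.075×, C7 at 0.21× height along it) — only T10
and C7 matter downstream. Standing curvature is −35° (lordotic), chosen as
anatomically typical for a standing L1–L5 circle-fit angle and so that the
per-FSU increment (a quarter of the commanded angle) never exceeds 14° at
the exercise extremes. Exercise waveforms command *relative* curvature:
static holds at −17.9° (COB), −15.0° (SHO), −18.3° (CUP) with 3 s
raised-cosine rise/fall transients around a 20 s hold (STA holds 0° for
exactly 20 s with no transients); dynamic exercises oscillate as a pure
0.25 Hz raised cosine between −13.7° and +32.0° (FE) or +34.9° and +57.3°
(F), five cycles in 20 s, with the recording starting mid-range one
quarter-cycle before the first extension extreme so that all extrema are
interior and locally symmetric. Each participant scales these extremes by a
flexibility factor drawn uniformly from [0.6, 1], spanning toward — but
never beyond — the commanded extreme range. Trunk lean (the tilt of the
S1–L1 chord off the pelvis longitudinal axis) co-varies with relative
curvature at 0.7°/° plus a per-exercise base lean, and thoracic tilt at
0.2°/°: people do not flex their lumbar spine while holding the torso
upright, and the co-varying lean is what gives captures of deep postures
their strong shared linear trend between models. The true intra-cycle
waveform of real athletes is unknown; the raised cosine is a modeling
choice, and per-frame ground truth (commanded curvature, lean, tilts,
event frames) is stored in every trial's metadata so recovery can always
be audited.

What the generator does **not** emulate: posture-dependent or
frequency-correlated soft-tissue artifact fields, muscle-driven dynamics,
out-of-sagittal-plane motion beyond isotropic noise, marker mislabeling.
Passing tests on this cohort therefore show that the *pipeline* is correct
and that the model-agreement conclusions hold under the stated geometry
and noise; they cannot certify behavior under structured skin-motion
artifact, which is the dominant open error source in real spine capture.

## Numerical choices and degenerate inputs

Polynomial fits use the QR solution of the Vandermonde system; captures
whose model markers are non-monotone in $u$ (a spine folded past the
pelvis axis) or have duplicate $u$ are rejected per capture with an error,
not fitted. Circle fitting switches to the straight-spine path when the
points' smallest singular value indicates collinearity below tolerance.
Report rounding is half-away-from-zero at 2 decimals. The pipeline is
deterministic given the generator seed — reruns are bit-identical — and
per-trial stage errors are logged with (participant, exercise) attribution
while the remaining trials continue.

Problem sizes used by the shipped analyses: the full cohort is 17
participants × 6 trials (≈ 2400–3120 frames each), giving 68 captures per
static exercise and per dynamic direction × percentage cell (17 × 4
cycles), 1632 captures in total; the curvature-recovery sweep uses 100
5-second static holds. These sizes match the study design the generator
emulates.

## Known limitations

* Model-agreement values on synthetic data reproduce the *structure* of
  real results (Model 3 vs 4 ≈ 1.00 everywhere; line-model pairs unstable
  where slopes change sign) but their exact means depend on the commanded
  waveforms, so only bound-type and structural statements are
  transferable.
* The C3D layer supports the Intel/float32 flavor it writes; integer-scaled
  or DEC-ordered files are rejected explicitly.
* Lateral-marker reconstruction assumes the lateral pairs move rigidly
  with the lumbar level they flank; under heavy soft-tissue artifact that
  assumption, like the markers themselves, degrades.
* The steady-window detector assumes one dominant hold per static trial;
  exercises with multiple distinct holds would need per-segment analysis.
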