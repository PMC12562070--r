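# lumbarseg

How many markers does it take to track the lumbar spine? In marker-based
motion capture of flexion–extension exercises — the kind of sagittal-plane
movements acrobatic athletes train — the lumbar spine can be modelled as one
rigid segment, as the two segments of a sparse marker set, or with a marker
on every vertebra. `lumbarseg` implements a complete analysis pipeline for
comparing four such marker-set models on the same captures:

| Model | Markers | Fit |
|-------|---------------------|-----|
| 1 | L1, L5 | first-degree polynomial |
| 2 | T10, S1 (Plug-in-Gait-style) | first-degree polynomial |
| 3 | L1, L3, L5 | second-degree polynomial |
| 4 | L1, L2, L3, L4, L5 | second-degree polynomial |

Each model's markers are projected into the pelvis-defined sagittal plane
and fitted with a polynomial `v(u)` over the longitudinal coordinate `u`.
All four curves are evaluated at five equidistant points of the capture's
lumbar span, and agreement between models is the per-capture Pearson
correlation of those ordinates, aggregated as mean ± SD per exercise and
movement phase. Lumbar curvature itself is quantified with the circle-fit
method: a circle is fitted to the five lumbar markers (Taubin's algebraic
fit; the circumcircle for three points) and the lordosis angle is the
central angle between the radii through L1 and L5, reported relative to the
participant's neutral standing value.

Because the kind of recordings this analysis targets are rarely shareable,
the package ships a first-class synthetic motion-capture generator: a
circular-arc lumbar chain (L1..L5 and S1 on one arc, equally spaced by arc
length) riding on a rigid pelvis, sampled at 120 Hz through six exercises —
static standing (STA), standing flexion–extension (FE, 5 cycles), sitting
flexion (F, 5 cycles), cobra (COB), shoulder-flexion stretch (SHO) and
cobra with arms up (CUP) — with Gaussian soft-tissue noise, random
occlusion gaps, and per-frame ground truth for every commanded pose.

The rest of the pipeline mirrors standard mocap practice: Vicon-style CSV
and C3D trial I/O, cubic-spline gap filling with lateral-marker
reconstruction of lumbar markers, fourth-order zero-phase Butterworth
low-pass filtering at 5 Hz, a pelvis anatomical frame from the PSIS/ASIS
markers, torso-angle (C7–S1 vs pelvis longitudinal axis) cycle detection
with phase sampling at 0/25/50/75/100 % of each flexion and extension
half-cycle, and four steady-state captures per static hold.

## Worked example

```r
library(lumbarseg)

cohort <- generate_cohort(n_participants = 3, seed = 7)   # 18 trials
res <- run_pipeline(cohort)
writeLines(format_report(res$report))
```

The report (abridged) is one row per exercise/phase cell, `mean ± sd` of the
per-capture Pearson correlation for each model pair, plus relative lumbar
lordosis in degrees:

```
cell               1 vs 2         1 vs 3         1 vs 4         2 vs 3         2 vs 4         3 vs 4         rel. lordosis (deg)
STA                1.00 ± 0.00   0.65 ± 0.02   0.65 ± 0.02   0.65 ± 0.02   0.65 ± 0.02   1.00 ± 0.00   0.00 ± 1.07
FE flexion 0%      1.00 ± 0.00   0.88 ± 0.01   0.88 ± 0.01   0.88 ± 0.01   0.88 ± 0.01   1.00 ± 0.00   -10.82 ± 1.81
FE flexion 25%     1.00 ± 0.00   0.82 ± 0.01   0.82 ± 0.01   0.82 ± 0.01   0.82 ± 0.01   1.00 ± 0.00   -5.35 ± 0.95
...
COB                1.00 ± 0.00   0.95 ± 0.00   0.95 ± 0.00   0.95 ± 0.00   0.95 ± 0.00   1.00 ± 0.00   -13.66 ± 1.82
CUP                1.00 ± 0.00   0.95 ± 0.00   0.95 ± 0.00   0.95 ± 0.00   0.95 ± 0.00   1.00 ± 0.00   -14.40 ± 2.90
```

Reading it: the two-segment Model 3 and the all-vertebrae Model 4 agree at
`1.00 ± 0.00` in every cell (per-capture minimum here 0.9994 over 288
captures), while the single-segment models agree with them only where the
posture makes the spine curve close to a line through its endpoints.
`STA` relative lordosis is 0 by definition — it is the reference posture.

```r
r34 <- subset(res$correlations, pair == "3v4")
min(r34$r)
#> [1] 0.999385
```

## Analysis workflow

The `analysis/` scripts run the full study on a simulated cohort and write
their tables under `results/`:

1. `01_simulate.R` — 17 participants x 6 exercises, 2 mm marker noise,
   occlusion gaps; trials as CSV with ground-truth sidecars (under
   `scratch/`, ~300 MB, regenerable).
2. `02_events.R` — preprocessing, torso-angle events, capture audit against
   generator ground truth.
3. `03_compare_models.R` — model fits, correlations, lordosis and the final
   report (`results/report.txt`, `results/captures.csv`).
4. `04_lordosis_recovery.R` — 100-pose curvature-recovery sweep at 2 mm
   noise (RMSE ≈ 0.6°).

## Vignette

`vignettes/lumbar-segmentation.Rmd` documents the model, the generator's
kinematics and defaults, numerical choices and known limitations.
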