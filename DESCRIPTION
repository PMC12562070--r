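Package: lumbarseg
Title: Lumbar Spine Segmentation Analysis for Marker-Based Motion Capture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for comparing lumbar spine marker-set models in
    sagittal-plane flexion-extension exercises captured with optical motion
    capture. Provides a synthetic motion-capture generator (circular-arc lumbar
    chain on a rigid pelvis with soft-tissue noise and marker gaps), Vicon-style
    CSV and C3D trajectory I/O, trajectory preprocessing (zero-phase Butterworth
    filtering, gap filling, lateral-marker reconstruction, pelvis anatomical
    frame, sagittal projection), torso-angle cycle and capture detection, four
    polynomial spine models with circle-fit lumbar lordosis, and per-capture
    Pearson model-agreement reports aggregated by exercise and movement phase.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
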