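# cprmeter

Video-based measurement of chest-compression quality for
cardiopulmonary resuscitation (CPR), built around a fixed-length
fluorescent **marker wristband** worn by the rescuer. The package is
aimed at people building or validating camera-based CPR feedback
systems (for example on an AED-mounted camera): it turns a tracked
detection box into compression **depth, count and frequency**, checks
rescuer **posture** from externally estimated keypoints, and ships a
lightweight anchor-based **marker detector** plus a synthetic-scene
generator that closes the measurement loop for end-to-end validation.

## The idea

A single camera has no absolute depth scale. A marker of known
physical length `M` (default 33.40 cm) restores it through the pinhole
geometry with focal length `L'` in pixels:

```
L = M * L' / Ap          # camera-to-marker range from apparent length Ap
Bp = f * B0              # window-resolution displacement -> native resolution
H = Bp * L / L'          # vertical pixel displacement -> depth in cm
```

Compressions are then complete peak–trough–peak excursions of the
vertical displacement signal, found by a prominence (hysteresis)
detector; each cycle's pixel amplitude maps to a per-cycle depth in
centimetres through the two equations above.

The detector ("CPR-Detection" style) is a ShuffleNetV2 backbone with
mixed local channel attention (MLCA), a small-target feature pyramid
(STD-FPN) fusing stride-8 and stride-32 maps, and partial-convolution
(PConv) heads, implemented with the package's own small autodiff over
base-R arrays; parameter/FLOP accounting, precision/recall and mAP
evaluation are included, and each architectural addition can be
ablated independently.

## Worked example

Simulate a 100-compression trial under the default noise model
(5 cm stroke, 110 per minute, camera 60 cm away, 1 px tracking noise,
2% dropped detections), then measure it back:

```r
library(cprmeter)

sp  <- scene_spec()                                   # study conditions
sim <- simulate_track(sp, n_compressions = 100, seed = 1)
m   <- measure_track(sim$track, sp$cam, sp$rmap, sp$marker_length_cm)
m$metrics
#> CPR quality metrics
#>   compressions : 100 over 54.7 s
#>   frequency    : 109.8 per minute
#>   mean depth   : 5.01 cm (100 cycles with depth)

ev <- evaluate_accuracy(m$metrics, sim$truth$metrics)
ev$depth_accuracy      # fraction of cycles with depth error < 1 cm
#> [1] 1
ev$count_error
#> [1] 0
```

The count is recovered exactly, the frequency matches the generated
110 per minute, and every per-cycle depth lands within 1 cm of the
generated stroke (typical errors are 0.1–0.3 cm at this noise level).
With all noise switched off the recovered depths agree with the
generated strokes to below 1e-6 cm — the geometry is exact, so any
residual error comes from tracking noise, not the mapping.

Posture checks consume pose-estimator keypoints (OpenPose-style JSON)
and flag the three classic faults — non-vertical arms, one-knee
stance, low arm visibility:

```r
kps <- synth_keypoints("one_knee", n_frames = 60, seed = 1)
assess_posture(kps)
#> Posture report over 60 frames
#>   non-vertical arm :  0.0% of frames
#>   one-knee stance  : 100.0% of frames
#>   low visibility   :  0.0% of frames
```

A thin command-line front end over the same functions lives at
`inst/cli/cprmeter.R` (subcommands `simulate`, `measure`, `posture`,
`train`, `detect`, `accept`).

## Package layout

* `R/camera.R` — pinhole model, projection, the marker depth mapping
* `R/track.R`, `R/cycles.R` — box tracks, displacement series,
  cycle detection, metrics, accuracy evaluation
* `R/nn-tape.R`, `R/detector*.R` — array autodiff, the detector,
  training, decoding, mAP
* `R/scene.R`, `R/render.R` — analytic trial simulation; rendered
  frames, augmentation, dataset splits
* `R/keypoints.R` — posture rules and keypoint fixtures
* `R/pipeline.R` — end-to-end measurement and the trial battery
* `vignettes/cpr-measurement.Rmd` — the methods vignette: model,
  assumptions, parameter choices, limitations
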