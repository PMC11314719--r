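---
title: "Measuring chest-compression quality from monocular video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring chest-compression quality from monocular video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cprmeter)
```

## The measurement problem

During cardiopulmonary resuscitation the three quantities that define
compression quality are depth (target roughly 5--6 cm), rate (target
100--120 per minute) and count. A single camera cannot measure depth
directly -- monocular video has no absolute scale. `cprmeter`
implements the solution of wearing a fluorescent marker wristband of
known physical size (33.40 cm x 3.80 cm by default) on the rescuer's
arm. The marker plays two roles at once: it is an easy, high-contrast
target for a lightweight object detector, and its known length turns
pixels into centimetres.

## The depth geometry

Under the pinhole model with focal length $L'$ in pixels, a marker of
physical length $M$ at horizontal range $L$ from the camera appears
with pixel length $A_p$, and similar triangles give

$$L = \frac{M \, L'}{A_p}.$$

A vertical displacement of the marker by $H$ centimetres at that range
moves its detection box vertically by $B_p$ pixels (at the camera's
native resolution), with

$$H = \frac{B_p \, L}{L'}.$$

Because detection runs at a processing-window resolution rather than
the camera's native one, window displacements $B_0$ are first rescaled
by the ratio of vertical resolutions, $B_p = f\,B_0$. These three
relations are the whole calibration: no stereo rig, no depth sensor,
no per-session calibration procedure beyond knowing the camera's pixel
focal length.

Two conventions deserve note. First, the printed relation between $L$,
the marker half-displacement and the half-angles is circular if taken
alone (the range appears on both sides once the tangents are
substituted); the fixed marker length is what actually anchors the
scale, so `estimate_range()` computes $L = M L' / A_p$ directly and
the displacement mapping is applied verbatim afterwards. Second, $L'$
is taken to be the *vertical* pixel focal length, since compressions
displace the marker along the image v-axis; square pixels make the
distinction moot.

Assumptions: an ideal pinhole (no lens distortion), a camera whose
optical axis is roughly horizontal so the compression stroke is
vertical in the image and the camera-to-marker depth is constant
through the stroke, and a marker worn so its long axis stays roughly
parallel to the image plane. Within these assumptions the mapping is
exact: the package's closed-loop test recovers a synthetic stroke to
better than $10^{-6}$ cm with all noise switched off.

## From box track to cycles

The tracked detection box gives a vertical position time series.
`extract_displacement()` rescales it to the native resolution, fills
detection gaps up to 0.25 s by linear interpolation (longer gaps are a
broken track and raise an error naming the interval), and applies a
centred moving average (default window 0.1 s).

`detect_cycles()` finds compressions with a hysteresis rule: a local
maximum is confirmed as the top of a stroke only after the signal has
fallen at least `min_amplitude_px` below it, and symmetrically for the
bottom; this is equivalent to requiring that prominence and makes the
detector immune to pixel jitter below the threshold. One complete
top--bottom--top excursion is one compression. Defaults:

* `min_amplitude_px`: 25% of the trace's typical peak-to-trough
  excursion, estimated as the 5%--95% quantile range of the smoothed
  post-warm-up signal. A fixed fraction of the observed excursion makes
  the threshold scale-free (the same trial filmed closer simply scales
  all pixel quantities).
* `min_period_s = 0.3` s, which caps the plausible rate at 200 per
  minute.
* `warmup_s = 2` s: compressions whose bottom falls in the first two
  seconds are discarded. Early frames are dominated by the marker
  settling on the wrist rather than by compressions; the synthetic
  scenes reproduce this with a low-amplitude lead-in wobble.

Two numerical choices matter for accuracy. Extremum *positions* are
located on the smoothed signal, but extremum *values* are read from
the unsmoothed series: a moving average attenuates a 110-per-minute
sinusoid by several percent, which would bias every depth low if
amplitudes were read from the smoothed curve. And because the frame
grid rarely samples the exact extremum, the extremum value is refined
by a three-point parabola; at 30 fps this reduces the sampling bias
from roughly 0.05 cm to below 0.01 cm, and it is exact when an
extremum happens to be sampled.

Depth is then computed per cycle: the marker's apparent length is
averaged over the cycle's frames (damping per-frame jitter) to give
the range, and the cycle's raw amplitude is mapped through the
geometry. Cycles with no usable marker-length observation are flagged
`depth_available = FALSE` rather than dropped. Frequency is reported
over the active compression span, measured trough-to-trough and scaled
by $n/(n-1)$, which is insensitive to where exactly the opening peak
of the first cycle sits.

The accuracy conventions follow the reported claims: a per-cycle depth
is "accurate" when its absolute error is strictly below 1 cm, and a
trial's count is correct when it is within two compressions
(inclusive); both bounds are configurable in `evaluate_accuracy()`.

## The synthetic scene generator

The `scene_spec()` defaults define the study conditions everything
else is validated under: marker 33.40 x 3.80 cm; camera with a 600 px
focal length and 704 x 704 native frame, detection window 352 x 352;
camera range 60 cm (the middle of the 50--75 cm band where an AED unit
typically sits); stroke 5 cm at 110 per minute; and a noise model with
1 px box-centre jitter, 1% marker-length measurement noise, 2%
detection dropout, 0.2 cm per-cycle depth variability, 2% period
jitter, and a 2 s settling lead-in of 0.2 cm wobble. The noise levels
are desk-scale stand-ins for the error sources observed in practice
(camera angle and lighting changes); they were chosen once to be
plausible for a stationary AED-mounted camera and are not revisited.

`simulate_track()` is analytic: per-cycle cosine strokes projected
through the same pinhole model the measurement inverts, with ground
truth recorded before noise. This closes the loop exactly, so the test
suite can assert recovery rather than plausibility. What the generator
deliberately does *not* emulate: rolling shutter, motion blur,
perspective foreshortening of a tilted marker, correlated tracking
failures, or a detector's systematic localisation bias. Passing the
closed-loop tests therefore validates the measurement chain, not any
particular tracker.

`render_frames()` produces the image side: a marker rectangle at its
projected size over a cluttered background including marker-coloured
distractors, with illumination jitter; labels are the drawn pixel
footprint. `augment()` applies the transform families used for
training data (rotation, both flips, scaling, colour jitter) at a
default factor of 6, chosen to match the 1479-to-8874 dataset
expansion; `split_dataset()` partitions 8:1:1 by largest-remainder
apportionment (the printed 7081/897/896 split is not an exact 8:1:1 of
8874 and cannot be reproduced from the stated procedure, so the
apportionment rule is documented rather than imitated).

## The marker detector

`detector_config()` describes a lightweight anchor-based detector in
the Yolo-FastestV2 lineage: a ShuffleNetV2 backbone (0.5x widths,
stages of 4/8/4 shuffle units at strides 8/16/32), mixed local channel
attention (MLCA) on each stage output, a small-target feature pyramid
(STD-FPN) that pools the stride-8 map by four and concatenates it with
the stride-32 map for one head while upsampling the stride-16 map onto
the stride-8 map for the other, and decoupled heads whose convolution
blocks use partial convolution (PConv: a 3x3 convolution over the
first quarter of the channels, identity on the rest). Each of the
three additions toggles off independently, reverting to the two-level
upsample-and-fuse pyramid and depthwise-separable head blocks of the
baseline.

Hyperparameters the architecture description leaves open were fixed
as follows: PConv ratio 1/4 (the convention of the partial-convolution
literature); MLCA local grid 2 x 2 with kernel-3 cross-channel 1-D
convolutions and nearest-neighbour unpooling; "globally pooled by a
factor of four" read as 4 x 4 average pooling with stride 4 (a true
global pool would collapse to 1 x 1 and could not be concatenated with
the stride-32 map); pyramid and head widths chosen so the full model
and the baseline land near the reference parameter scales (about 202 K
and 233 K parameters). Anchors come from k-means over training-set
box shapes, three per head.

The network is implemented in a small define-by-run reverse-mode
autodiff over base-R arrays (im2col plus BLAS matrix multiplication
for convolutions, nine shifted elementwise products for depthwise
convolutions), written for clarity and desk-scale problem sizes.
`train_toy()` is exactly what its name says: an Adam loop meant to
overfit tens of synthetic frames as a correctness check of the whole
computation graph -- gradients are verified against finite differences
in the test suite -- not to produce deployable weights. Assignment
follows the family's practice with adaptations for an elongated
marker: a ground truth matches every anchor whose width/height IoU
exceeds 0.35, lands in its centre cell (neighbouring cells along a
uniform bar see near-identical features and cannot be asked for
different offsets, so they are not positives), offsets decode as
$2\sigma - 0.5$, and box-covered cells that are not positives are
excluded from the negative objectness loss. The objectness target at
a positive is the IoU of the currently decoded box with its ground
truth, so a head that cannot localise precisely learns a
proportionally lower confidence; boxes under 5% of the image area are
assigned to the stride-8 small-object head only, whose cells are fine
enough to place them. The background class logit is lightly
supervised so it cannot inflate background scores. After training, a
recalibration pass settles the batch-norm running statistics on the
final weights.

Training defaults keep the reference learning rate 0.001 and use
batch 16 (the printed 512 only makes sense on datacentre hardware).
The overfitting *validation* deliberately departs from those
defaults: full batch (stationary batch-norm statistics) at learning
rate 0.01 for 600 epochs. The reason is a property of Adam worth
recording: its per-parameter step is about one learning rate per
iteration, so over a run the logits can only travel roughly
`steps x lr` units -- at 0.001 and a few hundred steps that is ~0.5,
nowhere near the +-3 a saturated objectness needs. The printed rate
suits schedules with very many steps; a desk-scale overfit needs a
correspondingly larger one.

Parameter counts are exact trainable-element counts; FLOP counts are
convolution multiply--accumulates for one forward pass (the reference
tables are internally inconsistent about FLOP units by a factor of
1000, so FLOPs are reported but never asserted against). Evaluation
uses the standard detection metrics: precision $TP/(TP+FP)$, recall
$TP/(TP+FN)$ (zero denominators return 0 with a warning), and mAP by
101-point interpolated precision--recall integration with greedy
score-ordered matching, averaged over IoU 0.5--0.95 for the stricter
summary.

## Posture rules

The three incorrect-posture scenarios are computable rules over
externally estimated keypoints (the package reads the common
multi-person JSON layout; pose estimation itself is out of scope):
non-vertical compression arm (shoulder-to-wrist angle from image
vertical above 15 degrees), one-knee stance (knee height gap above 15%
of torso length), and low arm visibility (mean arm-joint confidence
strictly below 0.3, the typical signature of dark clothing against a
dark background). The thresholds are design choices -- no quantitative
definitions exist to inherit -- validated against the keypoint
generator's scenarios (`synth_keypoints()`), which embody each fault
at a magnitude well past the threshold (arm angles 25--40 degrees,
knee gaps near 40% of torso). A one-second majority vote suppresses
single-frame jitter. The compressing arm defaults to the one whose
wrist sits lower in the image, with an explicit override.

## Problem sizes and determinism

The validation battery runs 50 trials of 100 compressions (a few
seconds in total); the detector tests use a reduced configuration
(96 px inputs, one shuffle unit per stage) whose toy training overfits
50 rendered frames in a couple of minutes; the full 352 px reference
configuration is built for parameter/FLOP accounting and shape checks.
These sizes were chosen so the whole suite runs comfortably on one
CPU. Every stochastic step takes an explicit seed, and the tests
assert bitwise reproducibility of tracks, label files, keypoints and
training losses under seed reuse.

## Known limitations

* Depth accuracy degrades with marker tilt: a marker pitched out of
  the image plane shortens its apparent length and inflates the
  estimated range. The per-cycle averaging damps jitter but not a
  systematic tilt.
* The cycle detector assumes a quasi-periodic signal; chaotic
  interrupted compressions are counted conservatively (an excursion
  must complete top-bottom-top to count).
* The toy training loop is single-threaded R; it validates
  correctness, not speed, and its mAP on 50 overfitted frames says
  nothing about generalisation to real video.
* Posture thresholds are fixture-validated defaults, not clinically
  calibrated values.
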