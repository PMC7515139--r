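---
title: "Recognising emotions from skeletal movement: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognising emotions from skeletal movement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Bodily movement carries emotional information: a joyful hop, a fearful
retreat with hands near the head, the near-stillness of a neutral stance.
`affmotion` classifies seven basic emotional states — neutral, sadness,
surprise, fear, anger, disgust, happiness — from sequences of 25-joint
skeletal tracking data of the kind produced by depth sensors such as the
Kinect v2. Each frame holds a 3D position (meters, sensor frame) for every
joint and a 3-angle orientation (degrees) for the joints the sensor can
orient (head, hands, knees and feet carry none).

The design philosophy is minimal preprocessing over engineered features:
the classifier input is a *sequence* of low-level joint states, not a bag
of whole-recording summaries, because complex, non-repeatable emotional
gestures are poorly captured by global statistics. A handcrafted-feature
baseline (`extract_baseline_features()` with classic classifiers) is
included precisely to make that comparison.

# Pipeline

## Body-local projection

Sensor coordinates depend on where the subject stood. `to_body_frame()`
projects each frame into a body-local frame anchored at the SpineBase
root: `p_local = t(R_root) %*% (p - p_root)`, with u pointing to the
subject's left, v up, w forward. The root itself is replaced by a
*root-delta* channel — displacement and rotation relative to the first
frame — so whole-body events (hops, squats, backing away) are preserved
rather than projected out.

The sensor reports orientations as three per-axis Euler angles without
documenting a composition order. We adopt intrinsic yaw(v)–pitch(u)–
roll(w) (`euler_order = "yxz"`), expose the order as an argument, and
note that every invariance property (rigid-motion invariance, isometry)
holds for any fixed convention. Non-root orientations are re-expressed
relative to the root by default (`relative_orientations = FALSE` keeps
sensor-frame angles), since the projected pose is otherwise mixed-frame.
Gimbal-adjacent root angles (cos of the pitch near zero) fall back to the
previous frame's rotation — continuity over failure — with identity for a
degenerate first frame.

## Keyframe extraction

`simplify_trajectory()` implements recursive curve simplification
(Lowe / Douglas–Peucker): starting from the chord between a trajectory's
endpoints, split at the point of maximum perpendicular distance when that
distance exceeds the *error rate*, and recurse. Design choices the
algorithm statement leaves open:

* **Deviation metric** — perpendicular Euclidean point-to-segment
  distance in 3D, the standard criterion for a 3D trajectory curve.
* **Tie-breaking** — the lowest index wins among equally-far points.
  This makes the split tree independent of the error rate, which yields
  the *nestedness* property (the keyframe set at a larger tolerance is a
  subset of the set at a smaller one) that the test suite verifies.
* **Multi-joint merging** — simplification runs per joint;
  `extract_keyframes()` takes the union over the 19 non-hand joints by
  default (a frame is key if salient for *any* joint), with
  `merge = "per_joint"` available. The root contributes its displacement
  channel, so jumps generate keyframes.
* **Error rate** — default 0.03 m, with 0.05 m the other recommended
  value. Below 0.03 m the tolerance is at the scale of sensor noise and
  nearly every frame survives; above 0.05 m most recordings collapse to
  their endpoints ("around 2" keyframes). Values outside [0.03, 0.05]
  work but warn.
* **Coordinate space** — keyframes are extracted on body-local (not yet
  scale-normalised) trajectories, so the metric tolerance keeps its
  physical meaning in meters.

## Scale and z-score normalisation

Taller subjects produce larger coordinates. `compute_subject_scale()`
estimates a per-subject scale as the **median SpineBase–SpineShoulder
distance over all frames of the subject's neutral recordings** — these
two joints are the least noisy, and using the *neutral* recordings pins
the scale to the resting skeleton so emotional whole-body motion is not
normalised away. `scale_normalize()` divides all root-relative positions
(and the root displacement) by this length; orientations are angles and
need no rescaling.

Recordings have different keyframe counts, so `pad_sequences()` appends
zero rows up to the corpus maximum and keeps a pad mask.
`zscore_normalize()` standardises per feature with moments pooled over
the **real rows of all sequences** (sequence-wise normalisation);
"mean and standard deviation" could also be read as one global scalar
pair, so `per_feature = FALSE` provides that reading. Padded rows stay
exactly zero. Zero-variance features (e.g. the zero-filled orientation
channels of joints the sensor cannot orient) standardise to zero with a
warning rather than erroring. Within cross-validation the moments are
fitted on the training folds only and applied to the test fold — the
leak-free choice; `normalize_scope = "corpus"` restores whole-corpus
statistics.

## Quantity of motion

`quantity_of_motion()` summarises joint involvement per emotion: the
average, over recordings of an emotion, of each joint's mean
per-transition displacement in *hierarchical local coordinates* (each
joint relative to its parent in the skeleton tree, rotated into the
parent's orientation frame where one exists). Two small ambiguities are
resolved as follows: the joint index range is taken as the 25 tracked
joints (0–24), and the per-recording normaliser is the number of
*transitions* F−1 (`normalize_by = "frames"` divides by F instead).
On real sensor data the hand and thumb joints dominate this statistic
because of measurement error — which is exactly why the feature sets
exclude them; `qom_heatmap(..., exclude_hands = TRUE)` reproduces the
hands-excluded view in which wrists and arms dominate.

## Feature sets

`compose_features()` builds the keyframes × features matrix for six set
ids: P/O/PO crossed with full-body (19 non-hand joints) or upper-body
(11 joints, suffix U). Position channels come from the scale-normalised
body-local pose (root = displacement channel); orientation channels are
zero-filled where the sensor reports none, keeping the matrix
rectangular. The standard widths are P = O = 58, PO = 115, PU = OU = 34,
POU = 67: each is 3 (or 6) channels per joint **plus one**, and since
PO = P + O − 1 there is exactly one extra channel *shared* between the
position and orientation blocks. We implement it as the keyframe
timestamp normalised to [0, 1] — a temporal index is the natural shared
per-keyframe channel, and it reproduces all six widths.
`temporal_channel = FALSE` gives the pure 57/114-column variant with a
warning that the widths then deviate.

# Classifiers

No R deep-learning framework is assumed: the three sequence classifiers
are implemented in the package directly as matrix code, with analytic
gradients verified against numeric differentiation in the test suite.

* **CNN** — the padded feature matrix is treated as a one-channel image;
  3×3 convolutions (stride 1, same padding), ReLU, and 2×2 max pooling
  after each of three convolution layers (default widths 250, 250, 100),
  then a dense layer of 100 units. Kernel and pooling geometry are not
  dictated by the architecture summary we follow; 3×3/2×2 is the
  smallest standard choice.
* **RNN** — three tanh recurrent layers (300, 150, 100) with
  backpropagation through time.
* **LSTM** — three LSTM layers (250, 300, 300); forget-gate biases start
  at 1.

All end in a dense softmax output of 7/6/4 units. Training uses ADAM on
cross-entropy, at most 500 epochs with early stopping after 30 epochs
without loss improvement (minimum delta 1e-4, monitored on training loss
— no validation split is part of the protocol). Unstated
hyper-parameters follow common defaults: learning rate 1e-3, batch size
32, global gradient-norm clipping at 5 for the recurrent models (the
classic vanishing/exploding-gradient mitigation). Recurrent models
freeze their state across padded steps via the mask, so the final state
is the state at each sequence's last real keyframe; the CNN consumes the
zero padding as-is. Given a seed, initialisation and training are
deterministic.

## Cross-validation

"10-fold leave-one-subject-out" with 16 subjects cannot be taken
literally, so `subject_grouped_cv()` partitions *subjects* into 10 folds
(with 16 subjects: six folds of two and four folds of one) and supports
strict LOSO via `folds = "loso"`. No subject ever appears on both sides
of a fold — asserted structurally in the tests. Each iteration
reshuffles the fold assignment; the reported score is the
sample-weighted mean accuracy over folds and iterations (fold-weighted
averaging would differ only through unequal fold sizes).

# The synthetic corpus

The package is developed and tested against a synthetic corpus because
the kind of acted emotional-gesture database the method targets is
distributed on request only. `generate_corpus()` emulates the target
design: 16 subjects × 7 emotions × 5 repetitions = 560 recordings
(80 per emotion), 3.5–5 s at 30 fps, subject heights 1.55–1.92 m.

The motion model is forward kinematics over the 25-joint tree — not a
physics simulation. Per-emotion *archetypes* drive sinusoidal joint
rotations (shoulders/elbows dominant, knees visibly involved, in line
with the hands-excluded involvement pattern), with a distinct amplitude
and tempo per emotion, static posture biases (head droop for sadness,
raised arms for surprise/happiness), and root events (hops for
happiness, backing away for fear and disgust). Fear and disgust
deliberately share the "backing out, hands near head" motif so that
their mutual confusion — the qualitative structure observed on real
data — is reproducible. Amplitude, tempo and phase are jittered per
subject and repetition; an envelope ramps motion in and out of the rest
pose. Gaussian sensor jitter is added with σ = 2 mm on body joints and
12 mm on hand joints, mimicking the hand-tracking noise that motivates
the hand-joint exclusion, plus 0.4° of angular noise on the orientation
stream. Because motion is articulated, bone lengths are exactly
constant before jitter — a property the tests check.

Emitted joint orientations follow the sensor's bone-orientation
semantics: a joint's orientation is the rotation of the bone *into* it,
i.e. the cumulative rotation of the parent chain excluding the joint's
own actuation (the root emits its own rotation). This matters for the
quantity-of-motion statistic: in parent-local coordinates each joint
then moves with its own local angular velocity times its bone lever, so
the generator's involvement ground truth (wrists and arms dominant,
spine least, knees visible) is recoverable, exactly as on real data
where the orientation stream is not perfectly consistent with the
positional stream. Had orientations been emitted as the full cumulative
chain rotation, parent-local positions would be constant bone offsets
and the statistic would degenerate to sensor noise.

What the generator does *not* emulate: biomechanical realism,
within-class style diversity of real actors, occlusion artefacts, or
sensor dropout (a separate `degrade()` step simulates tracking failures
for the quality-rejection filter). Consequently, passing the end-to-end
recovery test shows that the pipeline preserves and recovers class
structure that is genuinely present in its input — it does not certify
any particular accuracy on real acted data, where reported accuracies
are far lower.

# Problem sizes and numerical choices

The test suite runs the full 560-recording corpus through the complete
pipeline once, and trains a single-layer 32-unit LSTM (batch size 128,
epoch cap 25, one CV iteration) for the recovery check — the
well-separated synthetic classes converge within a few epochs, so the
published three-layer widths would add compute without changing the
conclusion; unit tests use smaller corpora (two subjects, shortened
recordings). Other numerical details: softmax is computed with row-max
subtraction; cross-entropy clamps probabilities at 1e-12; Glorot-uniform
initialisation throughout; ADAM bias correction is applied; exact ties
in max pooling send the gradient to the first candidate; the farthest
point in curve simplification breaks ties toward the lowest index;
degenerate chord (coincident endpoints) falls back to point-to-point
distance.

# Known limitations

* The Euler-angle convention of real sensor exports must match the
  configured `euler_order`; only the default order supports angle
  extraction.
* The CNN requires the padded keyframe count and feature width to
  survive three halvings; very short corpora are automatically padded
  by the pooling layers but carry little signal.
* Training is single-threaded R matrix code: adequate for corpus-scale
  experiments (minutes), not for architecture sweeps (the 2–4-layer /
  50–400-unit search the defaults descend from is supported by
  configuration but not re-run here).
* `read_sequences()` assumes the documented CSV/JSON-lines schema;
  proprietary sensor containers (e.g. XEF) are out of scope. Sources
  providing only frame numbers are assumed to run at 30 fps.
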