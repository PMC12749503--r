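---
title: "Scoring rehabilitation exercises from pose keypoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring rehabilitation exercises from pose keypoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinescore)
```

## The problem and the model

Markerless human-pose estimators emit, for every video frame, 33 anatomical
landmarks as normalized coordinates plus a visibility confidence. For
home-based physiotherapy the question is not where the pixels are but
whether the patient moved *correctly*: through which joint angles, over
what range, at what speed, and for how many repetitions, compared with a
clinician's demonstration. kinescore answers that question from the
keypoint stream alone.

The central modelling commitment is **angular representation**: all
assessment is done on joint angles rather than raw coordinates. A joint
angle is defined by a (proximal, vertex, distal) landmark triplet and the
cosine rule,

$$\theta \;=\; \arccos\!\left(\frac{\mathbf a\cdot\mathbf b}
{\lVert\mathbf a\rVert\,\lVert\mathbf b\rVert}\right),
\qquad \mathbf a = p_{\text{prox}}-p_{\text{vertex}},\;
\mathbf b = p_{\text{dist}}-p_{\text{vertex}},$$

which is invariant to translation, rotation and uniform scaling of the
skeleton — exactly the disturbances (camera placement, subject distance,
frame jitter) that make raw-coordinate comparison fragile. From the angle
trajectory we derive range of motion $\mathrm{ROM}=\theta_{\max}-\theta_{\min}$,
angular velocity by central differences
$v(t) = \big(\theta(t{+}1)-\theta(t{-}1)\big)/(2\Delta t)$, repetition
segments, and the similarity scores below.

### Pipeline

1. **I/O and validation** (`read_pose_json`, `validate_sequence`): the
   structured JSON envelope (`Timeline/Items`, `TotalNumberOfFrames`,
   `Width`, `Height`, `AverageFPS`; per-landmark `x, y, z, visibility`).
   `z` is read and preserved but unused: every computation here is planar.
   The machine-readable schema ships in `inst/extdata/pose-schema.json`.
2. **Preprocessing** (`to_pixel`, `max_bounding_box`, `normalize_to_box`,
   `fill_low_visibility`, `smooth_series`): coordinates are converted to
   pixels, a *fixed maximum bounding box* — the union of all per-frame
   boxes — provides one constant reference frame for the whole recording,
   and short visibility dropouts are bridged by linear interpolation.
3. **Features** (`angle_series`, `range_of_motion`, `angular_velocity`,
   `standardize`): angles are computed on pixel (isotropic) coordinates.
   Box-normalized coordinates are anisotropic in general and distort
   angles, so they serve trajectory-level comparison only.
4. **Repetitions** (`detect_peaks`, `segment_repetitions`): peaks of the
   exercised joint's angle trajectory mark repetition midpoints; running
   the same detector on the negated signal finds the troughs that bound
   each cycle.
5. **Scoring** (`dtw_align`, `ncc`, `similarity_score`, `action_score`):
   paired repetitions are compared by dynamic time warping and normalized
   cross-correlation; the per-repetition $R_{\max}$ values average into a
   similarity $S$, which combines with the repetition-count accuracy into
   a 0–100 Action Score.
6. **Feedback** (`compare_joint`, `feedback_text`): clinician-style
   deviation tables and messages ("right knee flexing 110° less than
   demo").

## Key algorithmic choices

**Fixed vs per-frame bounding boxes.** A per-frame box re-anchors the
coordinate system every frame, so detection wobble in one outlier landmark
makes *every* landmark's normalized coordinates jitter. The fixed box is
the union of per-frame boxes (elementwise min of minima / max of maxima):
anchor-free, containing every frame, constant through time. The buffer
margin defaults to 5% of the larger frame dimension; the visibility
threshold for a landmark to influence the box is 0.5.

**Peak detection.** Local maxima are filtered by topographic prominence
(default 20% of the observed signal range — making counting invariant to
positive affine transforms of the angle signal) and a minimum separation
(default 0.25 s worth of frames). Plateaus resolve to their midpoint; when
two candidates crowd each other the more prominent wins. Sequence
boundaries act as *virtual troughs*, otherwise the first and last
repetitions of any real recording would be lost; a boundary repetition is
treated as complete by the stability filter when both endpoint angles sit
in the lower half of the segment's excursion.

**DTW.** The distance is classic dynamic programming over the symmetric
step set $\{(1,0),(0,1),(1,1)\}$ with squared pointwise cost; the reported
distance is the square root of the accumulated cost, so on the diagonal
path it reduces to the Euclidean distance between equal-length series,
which the warping can only improve on. Backtracking breaks ties
deterministically (diagonal first, then a step in the first series). DTW
is symmetric but not a metric; tests assert equality with brute-force path
enumeration on short series rather than metric axioms.

**NCC.** Cross-correlation uses full-series population moments with
overlap-length normalization, evaluated for lags up to 25% of the window
length. With global moments the $|R|\le 1$ bound is a property of the
operating regime (standardized windows, bounded lags) rather than a
theorem for arbitrary inputs at extreme lags; the property suite exercises
the default regime. Constant signals have no shape to correlate and yield
$R_{\max}=0$ with a flag instead of an error.

**The composite score.** The combination of similarity and count accuracy
into one number is this package's own design (the components are standard,
their blend is not):
$$\text{combined} = 100\cdot
\frac{w_s\max(S,0) + w_r\max(1-\text{err}/100,\,0)}{w_s+w_r},$$
with equal default weights. Anti-correlated motion clamps to zero rather
than driving the score negative, and every component is reported alongside
the composite so it stays auditable.

**Rounding.** Clinical tables round half away from zero (6.67 → 6.7,
−7.95 → −8), not by banker's rounding; `round_for_report` implements both
the integer and one-decimal modes. Two sign conventions for deviations
coexist in clinical reporting — range differences as demo − subject,
extreme-angle differences as user − ideal — and `compare_joint` preserves
both, labelled, rather than silently unifying them.

## The synthetic motion generator

Because pose recordings of patients are not shippable, every stage is
validated against `synthetic_motion_spec` / `generate_motion`: raised-cosine
angle cycles
$$\theta(t) = \text{baseline} + \tfrac{\text{rom}}{2}
\big(1-\cos(2\pi n_{\text{reps}} t/T + \phi)\big)$$
driven through a planar skeleton (standard anthropometric segment ratios,
configurable in `inst/extdata/skeleton.yaml`) into the full 33-landmark
layout. Raised cosine rather than sine so trajectories start and end at
the trough, making trough–peak–trough segmentation exact at the
boundaries. Corruption is layered on top, fully seeded: i.i.d. Gaussian
keypoint jitter, a shared sinusoidal whole-body drift (a translation, to
which angles are provably invariant), and visibility-dropout bursts.

What the generator emulates: multi-repetition single-plane exercises,
keypoint noise of the magnitude seen in consumer pose estimators
(coordinate jitter of a few pixels ≈ 1–2° of angle noise), camera drift,
intermittent occlusion. What it does not: soft-tissue artefact, true 3-D
kinematics and perspective, estimator biases that correlate across
landmarks, or irregular human tempo. Green tests therefore demonstrate
the *pipeline's* correctness and noise behaviour, not clinical accuracy
on real video.

### Study conditions used by the recovery suite

The acceptance suite drives a 100-run grid: repetitions 1–10, ROM 30–120°,
frame rate 30/60 fps, half the runs corrupted with jitter σ = 0.002
normalized units plus 20 px drift. Three conditions are the package's own
choices, fixed with these justifications:

* **Tempo: 3 s per repetition.** Published per-repetition statistics for
  these exercises (ROM ≈ 94° at ≈ 19.5°/s mean speed) imply ~10 s
  repetitions; 3 s is a conservative physiotherapy tempo. Very short
  recordings (~1.5 s per repetition) leave so few frames near each
  extreme that no estimator can pin ROM under realistic noise.
* **Baseline angle 45° (apex ≤ 165°).** The arccos angle lives in
  [0°, 180°]; as the apex approaches 180° the limb perpendiculars align,
  vertex noise is amplified (~0.8°/px here), and the fold at 180° biases
  every noisy measurement downward. That degeneracy is a property of the
  planar angle definition at full extension — documented as a limitation,
  and avoided in the grid so the grid measures the estimator, not the
  fold.
* **Noise level σ = 0.002** (≈ 2.6 px at 1280-px width) induces roughly
  1–2° of per-frame angle noise at the default skeleton's segment
  lengths, matching the "couple of degrees" regime of consumer pose
  estimators.

### ROM estimation under noise

`range_of_motion` is the definitional max − min and is the right estimator
for clean trajectories. On noisy data it is upward-biased by order
statistics alone: the maximum of ~900 jittered samples exceeds the true
apex by several times the per-frame noise. `estimate_rom` therefore reads
the angle at the *detected* repetition peaks and boundary troughs through
a local quadratic fit — window scaled to one eighth of the repetition
period, mirrored at sequence edges (a boundary anchor is itself an
extremum, so the signal is locally symmetric there) — and averages across
repetitions. One read per extreme per cycle: no order-statistics
inflation, and no moving-average apex bias because a quadratic matches the
local curvature. Anchors whose frames were never observed (dropout bursts)
are excluded rather than bridged.

## Degenerate inputs and numerical conventions

* Zero-length limb vectors raise a degenerate-geometry error; the caller
  marks the frame invalid.
* `arccos` arguments are clamped to [−1, 1] before evaluation.
* A constant angle series segments into zero repetitions (a valid
  outcome), standardizes to zeros with a flag, and correlates as 0.
* Degrees everywhere externally; radians only inside trigonometry.
* In-memory R objects index frames 1-based as R vectors do; every file
  format (JSON `Index`, CSV `frame` columns) is 0-based, with timestamps
  `index / fps`.
* Problem sizes in the test-suite: the recovery grid uses 100 runs of up
  to ~1800 frames; DTW oracle checks enumerate all warping paths for
  series of length ≤ 6 over 200 random pairs.

## Known limitations

* Strictly planar: out-of-plane motion projects into the camera plane and
  changes measured angles; multi-view fusion is out of scope.
* Angles near 0° or 180° are measurement-degenerate under keypoint noise
  (see above); reported reflex angles (> 180°) require the signed-angle
  convention of a specific protocol and are not produced by the default
  arccos form.
* The stability filter's trough-level heuristic assumes movements that
  return near their starting angle each cycle; exercises with drifting
  baselines would need per-exercise configuration.
* The composite Action Score's linear blend is a reporting convenience,
  not a clinically validated scale.
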