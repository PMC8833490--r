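---
title: "Methods: from detection streams to fox behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from detection streams to fox behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foxwatch)
```

## The monitoring problem

A single red fox lives in an enclosure watched by two cameras on
opposite narrow sides. An object detector upstream of this package
classifies each sampled frame into one of three postures — lying,
sitting, standing — with a confidence and a normalized center-format
bounding box. From nothing but that stream, the pipeline infers, second
by second, what the animal is doing: its activity level, its posture,
and the behavior obtained by crossing the two.

The pipeline has four stages, always in this order: (1) frame sampling
(index arithmetic; 5 fps by default from 15 fps native footage), (2)
per-camera posture smoothing and activity analysis, (3) camera fusion
on a shared 1 Hz grid, and (4) behavior classification and
aggregation. Smoothing *before* fusion matters: each camera's
systematic blind-spot errors are first reduced to a stable per-second
label with a meaningful confidence, and only then arbitrated between
cameras, which is what makes the blind-spot case (one camera sees a
lying fox where the other sees it standing) resolvable.

## Activity from box displacement

Between consecutive frames `f` and `f+1` the box center moves by
`m_{f,f+1} = sqrt((x_{f+1}-x_f)^2 + (y_{f+1}-y_f)^2)`, in normalized
image coordinates. Over a sliding window of 5 s stepped by 1 s the
mean vector norm is

```
m̄_t = (1/F) * Σ_{f=1}^{F-1} m_{f,f+1}
```

with `F` the number of frame slots in the window (25 at 5 fps). Note
the denominator: the sum runs over the `F − 1` pairs but is divided by
`F`. The activity thresholds were calibrated against exactly this
statistic, so `windowed_mean_norm()` implements it as printed; the
conventional mean over pairs is available behind
`activity_config(mean_over_pairs = TRUE)` but changes the statistic by
a factor `(F-1)/F` and should not be combined with the default
thresholds.

Thresholds (normalized units per frame pair): `m̄_t ≥ 0.0094` highly
active; `0.0054 ≤ m̄_t < 0.0094` active; otherwise inactive. The upper
boundary is inclusive by the published rule; inclusion of the lower
boundary in "active" is this package's convention (either choice
affects only values exactly equal to 0.0054, a measure-zero event for
real displacement data). No aspect-ratio correction is applied even
though a 1280×720 frame makes one normalized x-unit ≠ one y-unit in
centimetres: the thresholds were calibrated in the same uncorrected
space, so correcting the distances would silently invalidate them.

Windows are trailing (they end at `t`), so every sample is computable
in real time from frames already seen. Pairs count toward a window only
if both frames lie inside it. Gap handling is our convention, since
missed detections are unavoidable in practice: a pair touching a
missed frame is invalid, and a window observing fewer than half of its
expected pairs (`min_valid_fraction = 0.5`) reports no-data rather
than a mean dominated by the `1/F` normalization's downward bias.

## Posture smoothing, fusion, behavior

`smooth_posture()` replaces each second's posture by the most frequent
label in the trailing 5 s window; a single misclassified frame among
25 can never win. Ties (possible with sparse windows) go to the larger
summed confidence, then the fixed order lying < sitting < standing —
arbitrary, but deterministic, which we value more than any particular
choice.

`fuse_cameras()` works per second on the two smoothed streams: the
fused mean norm is the larger of the two (the camera seeing more of
the animal's motion is the more informative one), and on posture
disagreement the label with the higher confidence wins. If confidences
tie, the camera with the larger norm wins, then the fixed label order.
A second covered by one camera passes through; by neither is no-data.
Fusion is commutative and idempotent, and both properties are tested.

`classify_behavior()` crosses posture with activity. The ethogram has
seven labels: while all nine posture×activity combinations are
formally possible, sustained locomotion-level displacement is not
physically sustained while sitting or lying — it is entered and left
through those postures — so the default map folds "highly active
sitting/lying" into the "active" variants, reproducing the published
7-label ethogram. `behavior_map(strict_nine = TRUE)` keeps all nine
for users who want the literal cross product.

Posture changes are counted on the smoothed, fused 1 Hz series: a
change is two consecutive covered seconds with different labels,
binned by the later second; a no-data stretch between them suppresses
the count, because the animal may have changed posture any number of
times while unobserved. Half-hour bins are aligned to multiples of the
bin width from the stream origin.

## Detector evaluation

`evaluate_detections()` implements the classic VOC protocol: greedy
confidence-ordered one-to-one matching per image, a prediction being a
true positive iff an unmatched same-class ground-truth box overlaps it
with IoU ≥ 0.5 (equality counts), per-class 11-point interpolated AP,
mAP as the plain mean over classes, overall precision/recall from
pooled counts, and the mean IoU of matched pairs. Class-aware matching
is required for per-class AP to be meaningful. Zero-area degenerate
boxes get IoU 0 rather than an error so that a malformed prediction is
scored as a miss instead of aborting an evaluation run. Confidence
ties keep input order under a stable sort, making results reproducible
to the byte.

The 11-point AP is deliberately the interpolated 2007 variant — the
mean over recalls {0, 0.1, …, 1} of the maximum precision at or beyond
each recall — not the area-under-curve or 101-point COCO variants. Its
implementation is pinned against an independent brute-force oracle
(explicit PR-point enumeration and grid maximisation) on a thousand
random instances in the test suite, and the IoU closed form against a
pixel-grid counting oracle.

## The simulator: what it emulates, and what it does not

`simulate_truth()` draws behavior as a semi-Markov chain over the
ethogram (uniform jumps, exponential dwell with mean 60 s — long
against the 5 s windows, so few windows straddle a transition, while
still visiting many states per session) and moves the box center by a
fixed-length, uniformly directed step per frame, reflected inside the
arena. Step lengths default to 0.001 / 0.007 / 0.02 normalized units
per frame for the three activity regimes. These are calibration
constants, not fox biology: under the `1/F` window normalization a
constant step `s` gives a noiseless mean norm of `24·s/25`, i.e.
0.00096, 0.0067 and 0.0192 — each well inside its threshold band, with
enough margin that realistic detector noise (jitter inflates the
inactive norm, missed pairs deflate the active one) does not push a
regime across a boundary.

`render_camera()` adds the detector's failure modes: per-frame misses
(default 5%), isotropic center jitter (σ = 0.002, about 2.5 px
horizontally at 1280 px), and systematic posture flips with a flip
table — `c(standing = "lying")` models the blind-spot camera that
cannot see the legs. Flipped labels draw lower confidences (mean 0.6
vs 0.9), which is precisely the structure fusion exploits. Box sizes
are posture-typical constants with small jitter; only the center feeds
the activity statistic, the sizes exercise the IoU/evaluation paths.

The expected per-second labels bundled by `make_fixture()` are the
noiseless pipeline output on the truth trace — the same trailing
windows and the same mode filter, applied to perfect detections. The
alternative (labelling each second by the instantaneous generating
state) would charge every recovery test a fixed toll of
window-boundary seconds at each transition and measure mostly window
lag; against the noiseless reference, recovery accuracy isolates what
we actually want to measure, robustness to camera noise. The
instantaneous truth remains available per frame in the `TruthTrace`
for anyone who wants the stricter comparison.

What the simulator does **not** emulate: image content (no rendering),
correlated misses (occlusion bouts), camera-dependent geometry (both
cameras see the same normalized trajectory), enrichment objects,
caretaker events, or multiple animals. Passing recovery tests
therefore show that the *post-detector* pipeline is correct and
noise-robust under the stated noise model — they say nothing about
detector quality on real footage.

## Problem sizes and reproducibility

The test suite runs the recovery and fusion scenarios on 2 h sessions
(36,000 frames per camera at 5 fps), the oracle comparisons on 1,000
random AP instances and 500 random box pairs, and everything else on
seconds-to-minutes fixtures; the whole suite completes in well under
two minutes on one CPU. All randomness flows from explicit integer
seeds; identical seeds reproduce fixture files and pipeline reports
byte for byte, which the suite asserts.

## Known limitations

A motionless lying fox that is asleep and one that is awake are the
same to this pipeline. Pacing and enrichment interaction both appear
as "highly active standing". The `1/F` normalization biases window
means downward as coverage drops; the no-data rule bounds but does not
remove this. Thresholds are specific to the enclosure geometry,
camera placement and normalization used during their calibration and
do not transfer to other setups without recalibration.
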