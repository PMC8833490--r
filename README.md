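# foxwatch

Camera-based posture, activity and behavior monitoring for a singly
housed red fox (*Vulpes vulpes*), built for welfare monitoring in
enclosure studies where the animal is watched by two cameras mounted on
opposite narrow sides of the cage.

An object detector (e.g. a YOLO-family network) runs upstream and emits,
per sampled frame and camera, a posture class (`lying`, `sitting`,
`standing`), a confidence, and a normalized center-format bounding box.
`foxwatch` is everything downstream of that detector:

* **Activity analysis.** The per-frame displacement of the box center,
  `m_{f,f+1} = sqrt((x_{f+1}-x_f)^2 + (y_{f+1}-y_f)^2)`, is averaged
  over a sliding 5 s window stepped by 1 s,
  `m̄_t = (1/F) Σ_{f=1}^{F-1} m_{f,f+1}` with `F` frames per window,
  and thresholded into three activity levels:
  `m̄_t ≥ 0.0094` highly active, `0.0054 ≤ m̄_t < 0.0094` active,
  below that inactive.
* **Posture post-processing.** Per camera, a sliding 5 s mode filter
  removes single-frame misclassifications; the two cameras are then
  fused per second — the larger mean norm wins, and on posture
  disagreement the label reported with the higher confidence (this
  resolves blind-spot errors where one camera cannot see the legs).
* **Behavior classification.** A decision tree crosses posture with
  activity level into the 7-label ethogram (`highly active standing`,
  `active standing`, `standing still`, `active sitting`,
  `sitting still`, `active lying`, `lying motionless`), at one value
  per second; half-hour overviews tally time budgets and
  posture-change counts.
* **Detector evaluation.** IoU, greedy VOC-style TP/FP/FN matching at
  IoU ≥ 0.5, precision, recall, per-class 11-point interpolated AP and
  mAP; readers for YOLO/Darknet txt and Pascal-VOC XML annotations.
* **Simulation.** A ground-truthed generator (semi-Markov behavior
  states, reflected random-walk trajectory, per-camera miss/jitter/flip
  noise) so the entire pipeline is testable without video or trained
  weights.

## Worked example

Simulate one hour of two-camera observation with default noise
(5% missed detections, center jitter, blind-spot flips off), run the
full pipeline, and compare against the simulator's ground truth:

```r
library(foxwatch)

fx  <- make_fixture(sim_config(duration_s = 3600, seed = 1))
rep <- run_pipeline(fx$streams)
rep
#> fox monitoring report: 3600 s analysed, 3600 s covered (100.0%)
#> posture changes: 48
#> time budget (s):
#>   lying_motionless                  720
#>   sitting_still                     714
#>   standing_still                    236
#>   active_lying                      480
#>   active_sitting                    470
#>   active_standing                   405
#>   highly_active_standing            575

ok <- !is.na(rep$timeline$behavior)
mean(rep$timeline$behavior[ok] == fx$expected$behavior[ok])
#> [1] 0.985
```

The report bundles the 1 Hz timeline (`rep$timeline`: `t`, `posture`,
`level`, `behavior`), half-hour overview bins (`rep$overview`: seconds
per label per family plus posture-change counts), and a summary list.
98.5% of seconds are classified into the same behavior the simulator
actually generated; the misses sit at state transitions and under
heavier detector noise they grow gracefully.

Detector evaluation works from annotation files:

```r
truths <- read_yolo_labels("labels/", read_class_names("classes.names"))
evaluate_detections(preds, truths)   # per-class AP, mAP, precision, recall
```

A thin command-line wrapper with `simulate`, `activity`, `behavior` and
`evaluate` subcommands is installed at `inst/cli/foxwatch.R`.

## Scope

Video decoding, network training and the detector itself are out of
scope: detection streams (JSON Lines or CSV) are the interface.
Distinguishing sleep from motionless wakefulness is not attempted.
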