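#' Simulator configuration
#'
#' Describes a synthetic observation session: one fox in an enclosure,
#' watched by two opposing cameras, sampled at `fps` frames per second.
#' The animal moves through the seven-label behavior ethogram as a
#' semi-Markov chain with exponential dwell times; within a behavior
#' state the box center performs a reflected random walk whose
#' per-frame step length is fixed by the state's activity level.
#'
#' The default step lengths (0.001, 0.007, 0.02 normalized units per
#' frame at 5 fps) are calibrated so that the windowed mean norms of
#' the three regimes land well inside the inactive / active / highly
#' active threshold bands (cut points 0.0054 and 0.0094): under the
#' window's sum-over-F normalization a constant step `s` yields a mean
#' norm of `24 s / 25`, i.e. about 0.00096, 0.0067 and 0.0192. This is
#' a calibration of the test harness, not a claim about real fox
#' locomotion.
#'
#' @param duration_s Session length in seconds.
#' @param fps Sampling rate (default 5).
#' @param seed Integer seed; the whole fixture is a deterministic
#'   function of the config including the seed.
#' @param dwell_mean_s Mean dwell time per behavior state in seconds
#'   (default 60; long relative to the 5 s smoothing window so few
#'   windows straddle a transition).
#' @param step_sigma Named numeric: per-frame step length for
#'   `inactive`, `active`, `highly_active`.
#' @param margin Reflecting boundary inset keeping the box center away
#'   from the image edge.
#' @param strict_nine Simulate the 9-state ethogram instead of 7.
#' @param behaviors Optional character vector restricting the reachable
#'   behavior states (e.g. `"lying motionless"` for a sleeping-fox
#'   scenario); default all.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(duration_s = 600, fps = 5, seed = 1,
                       dwell_mean_s = 60,
                       step_sigma = c(inactive = 0.001, active = 0.007,
                                      highly_active = 0.02),
                       margin = 0.15, strict_nine = FALSE,
                       behaviors = NULL) {
  stopifnot(duration_s > 0, fps > 0, dwell_mean_s > 0,
            all(c("inactive", "active", "highly_active") %in%
                  names(step_sigma)),
            step_sigma["inactive"] < step_sigma["active"],
            step_sigma["active"] < step_sigma["highly_active"],
            margin >= 0, margin < 0.5)
  if (!is.null(behaviors)) {
    known <- behavior_states(strict_nine)$behavior
    if (!all(behaviors %in% known))
      stop("unknown behavior state(s): ",
           paste(setdiff(behaviors, known), collapse = ", "), call. = FALSE)
  }
  structure(list(duration_s = duration_s, fps = fps, seed = as.integer(seed),
                 dwell_mean_s = dwell_mean_s, step_sigma = step_sigma,
                 margin = margin, strict_nine = strict_nine,
                 behaviors = behaviors),
            class = "sim_config")
}

#' Per-camera noise configuration
#'
#' Noise model for rendering a camera's detection stream from the
#' ground-truth trace: missed detections, isotropic center jitter, and
#' systematic posture flips (the blind-spot effect — a camera that
#' cannot see the legs reports a standing fox as lying). Flipped labels
#' are reported with lower confidence than correct ones, mirroring a
#' detector that is less sure about a partially visible animal.
#'
#' @param camera_id Identifier for the stream.
#' @param miss_prob Per-frame probability of no detection (default 0.05).
#' @param jitter_sigma Per-axis standard deviation of center jitter in
#'   normalized units (default 0.002).
#' @param flip_prob Per-frame probability that a posture listed in
#'   `flip_table` is misreported (default 0).
#' @param flip_table Named character vector, e.g.
#'   `c(standing = "lying")`: truth label -> reported label.
#' @param conf_correct,conf_flipped Mean and sd of the (clipped-normal)
#'   confidence for correctly and incorrectly labeled detections.
#' @return A list of class `camera_config`.
#' @export
camera_config <- function(camera_id = "cam1", miss_prob = 0.05,
                          jitter_sigma = 0.002, flip_prob = 0,
                          flip_table = c(standing = "lying"),
                          conf_correct = c(mean = 0.9, sd = 0.05),
                          conf_flipped = c(mean = 0.6, sd = 0.1)) {
  stopifnot(miss_prob >= 0, miss_prob <= 1, jitter_sigma >= 0,
            flip_prob >= 0, flip_prob < 1,
            all(names(flip_table) %in% POSTURES),
            all(flip_table %in% POSTURES))
  structure(list(camera_id = camera_id, miss_prob = miss_prob,
                 jitter_sigma = jitter_sigma, flip_prob = flip_prob,
                 flip_table = flip_table, conf_correct = conf_correct,
                 conf_flipped = conf_flipped),
            class = "camera_config")
}

# behavior states with their posture and activity components
behavior_states <- function(strict_nine = FALSE) {
  map <- behavior_map(strict_nine)
  idx <- which(!duplicated(as.vector(map)))
  data.frame(behavior = as.vector(map)[idx],
             posture = rownames(map)[(idx - 1) %% 3 + 1],
             activity = colnames(map)[(idx - 1) %/% 3 + 1])
}

# typical normalized box size per posture (lying wide and low,
# standing tall); only the center feeds the activity statistic
POSTURE_BOX <- list(lying = c(w = 0.30, h = 0.12),
                    sitting = c(w = 0.16, h = 0.24),
                    standing = c(w = 0.26, h = 0.20))

#' Simulate a ground-truth trace
#'
#' Draws the behavior state sequence (semi-Markov chain, exponential
#' dwell times, uniform jumps to a different state) and the box-center
#' trajectory (reflected random walk with activity-dependent fixed step
#' length and uniform step direction). Deterministic given
#' `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `truth_trace`: `frames` (per frame:
#'   `frame_index`, `t`, `x`, `y`, `posture`, `activity`, `behavior`),
#'   `states` (the dwell segments), and `cfg`.
#' @export
simulate_truth <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  states <- behavior_states(cfg$strict_nine)
  if (!is.null(cfg$behaviors))
    states <- states[states$behavior %in% cfg$behaviors, , drop = FALSE]
  n_states <- nrow(states)
  segs <- list()
  t0 <- 0
  s <- sample.int(n_states, 1)
  while (t0 < cfg$duration_s) {
    dwell <- stats::rexp(1, rate = 1 / cfg$dwell_mean_s)
    segs[[length(segs) + 1]] <- data.frame(
      start_s = t0, end_s = min(t0 + dwell, cfg$duration_s),
      behavior = states$behavior[s], posture = states$posture[s],
      activity = states$activity[s])
    t0 <- t0 + dwell
    if (n_states > 1) {
      nxt <- sample.int(n_states - 1, 1)
      s <- if (nxt >= s) nxt + 1L else nxt
    }
  }
  segs <- do.call(rbind, segs)
  n_frames <- as.integer(round(cfg$duration_s * cfg$fps))
  tt <- (seq_len(n_frames) - 1) / cfg$fps
  seg_of <- findInterval(tt, segs$start_s)
  sigma <- cfg$step_sigma[segs$activity[seg_of]]
  theta <- stats::runif(n_frames, 0, 2 * pi)
  lo <- cfg$margin; hi <- 1 - cfg$margin
  reflect <- function(p) {
    # fold into [lo, hi] (steps are far smaller than the box, so a
    # single fold suffices; the loop guards pathological configs)
    while (any(p < lo | p > hi)) {
      p <- ifelse(p < lo, 2 * lo - p, p)
      p <- ifelse(p > hi, 2 * hi - p, p)
    }
    p
  }
  x <- numeric(n_frames); y <- numeric(n_frames)
  x[1] <- 0.5; y[1] <- 0.5
  for (f in seq_len(n_frames - 1)) {
    x[f + 1] <- reflect(x[f] + sigma[f] * cos(theta[f]))
    y[f + 1] <- reflect(y[f] + sigma[f] * sin(theta[f]))
  }
  frames <- data.frame(frame_index = seq_len(n_frames) - 1L, t = tt,
                       x = x, y = y,
                       posture = segs$posture[seg_of],
                       activity = segs$activity[seg_of],
                       behavior = segs$behavior[seg_of])
  structure(list(frames = frames, states = segs, cfg = cfg),
            class = "truth_trace")
}

# detection series reproducing the truth exactly (confidence 1)
perfect_series <- function(truth, camera_id = "truth") {
  fr <- truth$frames
  size <- do.call(rbind, POSTURE_BOX)[fr$posture, , drop = FALSE]
  detection_series(data.frame(
    frame_index = fr$frame_index, posture = fr$posture, confidence = 1,
    cx = fr$x, cy = fr$y, w = size[, "w"], h = size[, "h"]),
    fps = truth$cfg$fps, camera_id = camera_id)
}

#' Render a noisy camera stream from a ground-truth trace
#'
#' Applies the camera's noise model frame by frame: a miss produces an
#' explicit gap record; otherwise the reported center is the true
#' center plus isotropic Gaussian jitter (clipped to the unit square,
#' so clipping never moves a center further than the jitter did), the
#' posture is flipped according to the flip table with `flip_prob`, the
#' box size is the posture-typical size with small jitter, and the
#' confidence is drawn from the correct- or flipped-label confidence
#' model, clipped to `[0, 1]`. Deterministic given `seed`.
#'
#' @param truth A `truth_trace` from [simulate_truth()].
#' @param cam A [camera_config()].
#' @param seed Integer seed for this camera's noise.
#' @return A [detection_series()].
#' @export
render_camera <- function(truth, cam = camera_config(), seed = 1) {
  stopifnot(inherits(truth, "truth_trace"), inherits(cam, "camera_config"))
  set.seed(seed)
  fr <- truth$frames
  n <- nrow(fr)
  miss <- stats::runif(n) < cam$miss_prob
  cx <- pmin(1, pmax(0, fr$x + stats::rnorm(n, 0, cam$jitter_sigma)))
  cy <- pmin(1, pmax(0, fr$y + stats::rnorm(n, 0, cam$jitter_sigma)))
  posture <- fr$posture
  flip <- stats::runif(n) < cam$flip_prob & posture %in% names(cam$flip_table)
  posture[flip] <- unname(cam$flip_table[posture[flip]])
  size <- do.call(rbind, POSTURE_BOX)[posture, , drop = FALSE]
  w <- pmin(1, pmax(0.02, size[, "w"] + stats::rnorm(n, 0, 0.01)))
  h <- pmin(1, pmax(0.02, size[, "h"] + stats::rnorm(n, 0, 0.01)))
  conf_mean <- ifelse(flip, cam$conf_flipped["mean"], cam$conf_correct["mean"])
  conf_sd <- ifelse(flip, cam$conf_flipped["sd"], cam$conf_correct["sd"])
  confidence <- pmin(1, pmax(0, stats::rnorm(n, conf_mean, conf_sd)))
  rec <- data.frame(frame_index = fr$frame_index, posture = posture,
                    confidence = confidence, cx = cx, cy = cy, w = w, h = h)
  rec$posture[miss] <- NA_character_
  rec$confidence[miss] <- NA_real_
  rec$cx[miss] <- NA_real_; rec$cy[miss] <- NA_real_
  rec$w[miss] <- NA_real_; rec$h[miss] <- NA_real_
  detection_series(rec, fps = truth$cfg$fps, camera_id = cam$camera_id)
}

#' Build a complete ground-truthed two-camera fixture
#'
#' Simulates a truth trace, renders both camera streams, and computes
#' the per-second expected labels: the deterministic result of running
#' the analysis pipeline (mode smoothing, windowed mean norm, decision
#' tree) on the noise-free truth trace itself. Comparing pipeline
#' output on the noisy streams against these labels therefore measures
#' robustness to camera noise under identical temporal conventions,
#' rather than mixing in the bookkeeping lag any trailing window
#' introduces at state transitions.
#'
#' @param cfg A [sim_config()].
#' @param cameras List of two [camera_config()]s.
#' @param dir If non-`NULL`, fixture files are written there:
#'   `<camera_id>.jsonl` detection streams, `truth.csv`,
#'   `expected.csv`, and a `config.json` echo.
#' @param act Activity configuration used for the expected labels.
#' @return A list of class `fox_fixture`: `truth`, `streams` (named
#'   list of two detection series), `expected` (per second: `t`,
#'   `posture`, `level`, `behavior`), and `paths` when written.
#' @export
make_fixture <- function(cfg = sim_config(),
                         cameras = list(camera_config("cam1"),
                                        camera_config("cam2")),
                         dir = NULL, act = activity_config()) {
  truth <- simulate_truth(cfg)
  streams <- list()
  for (i in seq_along(cameras)) {
    cam <- cameras[[i]]
    streams[[cam$camera_id]] <- render_camera(truth, cam,
                                              seed = cfg$seed + i)
  }
  map <- behavior_map(cfg$strict_nine)
  ideal <- process_camera(perfect_series(truth), act = act,
                          duration_s = cfg$duration_s)
  expected <- behavior_timeline(ideal, map = map, cfg = act)
  out <- list(truth = truth, streams = streams, expected = expected)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list()
    for (id in names(streams)) {
      paths[[id]] <- file.path(dir, paste0(id, ".jsonl"))
      write_detections(streams[[id]], paths[[id]])
    }
    paths$truth <- file.path(dir, "truth.csv")
    utils::write.csv(truth$frames, paths$truth, row.names = FALSE)
    paths$expected <- file.path(dir, "expected.csv")
    utils::write.csv(expected, paths$expected, row.names = FALSE)
    paths$config <- file.path(dir, "config.json")
    jsonlite::write_json(unclass(cfg), paths$config, auto_unbox = TRUE,
                         digits = NA)
    out$paths <- paths
  }
  structure(out, class = "fox_fixture")
}
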