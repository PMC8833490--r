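#' Activity-analysis configuration
#'
#' Bundles the windowing and threshold parameters of the activity
#' analysis. Defaults are the published calibration for fox enclosure
#' footage: a 5 s trailing window advanced in 1 s steps over the mean
#' per-frame-pair displacement of the bounding-box center, with a
#' mean-norm below 0.0054 scored inactive, 0.0054 up to (but excluding)
#' 0.0094 active, and 0.0094 or more highly active. Distances live in
#' raw normalized image coordinates — the thresholds were calibrated in
#' that same uncorrected space, so no aspect-ratio correction is
#' applied.
#'
#' @param window_s Window length in seconds (default 5).
#' @param step_s Step between successive windows in seconds (default 1).
#' @param tau_active Lower displacement threshold separating inactive
#'   from active (default 0.0054, normalized units per frame pair).
#' @param tau_high Upper threshold separating active from highly active
#'   (default 0.0094).
#' @param min_valid_fraction Minimum fraction of a window's expected
#'   frame pairs that must be observed (no gap on either side) for the
#'   window to produce a value; below it the window is reported as
#'   no-data (default 0.5).
#' @param mean_over_pairs The windowed statistic divides the sum of the
#'   `F - 1` pair displacements in a window of `F` frames by `F`
#'   (default, matching the calibration of the thresholds); set `TRUE`
#'   to divide by the number of observed pairs instead (the
#'   conventional mean).
#' @return A list of class `activity_config`.
#' @export
activity_config <- function(window_s = 5, step_s = 1,
                            tau_active = 0.0054, tau_high = 0.0094,
                            min_valid_fraction = 0.5,
                            mean_over_pairs = FALSE) {
  stopifnot(step_s > 0, window_s >= step_s,
            tau_active > 0, tau_high > tau_active,
            min_valid_fraction > 0, min_valid_fraction <= 1)
  structure(list(window_s = window_s, step_s = step_s,
                 tau_active = tau_active, tau_high = tau_high,
                 min_valid_fraction = min_valid_fraction,
                 mean_over_pairs = mean_over_pairs),
            class = "activity_config")
}

#' Per-pair displacement of the bounding-box center
#'
#' For every pair of consecutive sampled frames `(f, f + 1)` the
#' Euclidean distance between the box centers,
#' `sqrt((x[f+1] - x[f])^2 + (y[f+1] - y[f])^2)`, in normalized image
#' coordinates. Pairs where either frame is a gap (no detection) or the
#' frames are not consecutive in the sampling grid are flagged invalid
#' and excluded from windowing.
#'
#' @param series A [detection_series()].
#' @return Data frame with one row per consecutive frame pair:
#'   `frame_index` (the later frame), `t` (its timestamp), `value`
#'   (distance, `NA` when invalid), `valid`.
#' @export
displacements <- function(series) {
  n <- nrow(series)
  if (n < 2)
    return(data.frame(frame_index = integer(0), t = numeric(0),
                      value = numeric(0), valid = logical(0)))
  dx <- diff(series$cx)
  dy <- diff(series$cy)
  consecutive <- diff(series$frame_index) == 1
  detected <- !is.na(series$posture)
  valid <- consecutive & detected[-n] & detected[-1] & !is.na(dx) & !is.na(dy)
  data.frame(frame_index = series$frame_index[-1],
             t = series$timestamp[-1],
             value = ifelse(valid, sqrt(dx^2 + dy^2), NA_real_),
             valid = valid)
}

#' Windowed mean displacement norm and activity level
#'
#' Slides a trailing window of `cfg$window_s` seconds in steps of
#' `cfg$step_s` over the displacement series and reports, per window
#' end time `t`, the mean norm: the sum of the valid pair displacements
#' whose later frame falls in `(t - window_s, t]`, divided by the
#' number of frame slots `F` in the window (see
#' [activity_config()]`$mean_over_pairs`). Windows observing fewer than
#' `min_valid_fraction` of their expected pairs are emitted as no-data.
#' Windows trail (end at `t`), so every value is computable in real
#' time from frames already seen.
#'
#' @param d Displacement table from [displacements()].
#' @param cfg An [activity_config()].
#' @param fps Frames per second of the underlying series (default 5).
#' @param duration_s Total coverage in seconds; defaults to the last
#'   pair timestamp rounded up. Windows are emitted for
#'   `t = step_s, 2 step_s, ..., duration_s`.
#' @return Data frame with columns `t`, `mean_norm` (`NA` for no-data),
#'   `n_pairs`, `level` (factor over inactive/active/highly_active,
#'   `NA` for no-data).
#' @export
windowed_mean_norm <- function(d, cfg = activity_config(), fps = 5,
                               duration_s = NULL) {
  stopifnot(fps * cfg$window_s >= 2)
  if (is.null(duration_s))
    duration_s <- if (nrow(d) > 0) ceiling(max(d$t)) else 0
  if (duration_s < cfg$step_s)
    return(data.frame(t = numeric(0), mean_norm = numeric(0),
                      n_pairs = integer(0),
                      level = factor(character(0), levels = ACTIVITY_LEVELS)))
  ends <- seq(cfg$step_s, duration_s, by = cfg$step_s)
  eps <- 1e-9
  out <- lapply(ends, function(t) {
    # frame slots in (t - window_s, t]: indices i with i/fps in the window
    lo <- floor(fps * (t - cfg$window_s) + eps) + 1
    hi <- floor(fps * t + eps)
    n_slots <- max(0, hi - max(lo, 0) + 1)
    # a pair lies inside the window only if both its frames do, so the
    # earliest admissible later-frame slot is lo + 1 (and at least 1)
    expected <- max(0, hi - max(lo + 1, 1) + 1)
    in_win <- d$frame_index >= max(lo + 1, 1) & d$frame_index <= hi
    vals <- d$value[in_win & d$valid]
    n_valid <- length(vals)
    if (expected == 0 || n_valid < cfg$min_valid_fraction * expected)
      return(data.frame(t = t, mean_norm = NA_real_, n_pairs = n_valid))
    denom <- if (cfg$mean_over_pairs) n_valid else n_slots
    data.frame(t = t, mean_norm = sum(vals) / denom, n_pairs = n_valid)
  })
  out <- do.call(rbind, out)
  out$level <- classify_activity(out$mean_norm, cfg)
  out
}

#' Classify a mean displacement norm into an activity level
#'
#' Values of `tau_high` (0.0094) or more are highly active; values from
#' `tau_active` (0.0054) up to but excluding `tau_high` are active; the
#' rest are inactive. The upper boundary is inclusive by the published
#' rule; inclusion of the lower boundary in 'active' is this package's
#' convention. Vectorised; `NA` in gives `NA` out.
#'
#' @param mean_norm Non-negative mean norm value(s).
#' @param cfg An [activity_config()] supplying the thresholds.
#' @return Factor with levels `inactive`, `active`, `highly_active`.
#' @examples
#' classify_activity(c(0.005, 0.0054, 0.007, 0.0094))
#' @export
classify_activity <- function(mean_norm, cfg = activity_config()) {
  if (any(mean_norm < 0, na.rm = TRUE))
    stop("mean_norm must be non-negative", call. = FALSE)
  lev <- ifelse(is.na(mean_norm), NA_character_,
                ifelse(mean_norm >= cfg$tau_high, "highly_active",
                       ifelse(mean_norm >= cfg$tau_active, "active",
                              "inactive")))
  factor(lev, levels = ACTIVITY_LEVELS)
}
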