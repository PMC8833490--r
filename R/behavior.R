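#' The posture-by-activity behavior decision tree
#'
#' Crossing three postures with three activity levels gives nine
#' combinations; the published ethogram names seven behaviors, with
#' high activity while sitting or lying folded into the 'active'
#' variants (sustained locomotion-level displacement is not physically
#' sustained in those postures, only entered and left through them).
#' The default map reproduces that 7-label ethogram; `strict_nine =
#' TRUE` keeps all nine combinations distinct.
#'
#' @param strict_nine Keep 'highly active sitting' and 'highly active
#'   lying' as distinct labels instead of collapsing them.
#' @return A 3 x 3 character matrix indexed `[posture, activity]`.
#' @examples
#' behavior_map()["standing", "active"] # "active standing"
#' @export
behavior_map <- function(strict_nine = FALSE) {
  m <- matrix(NA_character_, 3, 3, dimnames = list(POSTURES, ACTIVITY_LEVELS))
  m["standing", ] <- c("standing still", "active standing",
                       "highly active standing")
  m["sitting", ] <- c("sitting still", "active sitting",
                      if (strict_nine) "highly active sitting" else
                        "active sitting")
  m["lying", ] <- c("lying motionless", "active lying",
                    if (strict_nine) "highly active lying" else "active lying")
  m
}

#' Classify behavior from a posture and an activity level
#'
#' Looks up the (posture, activity) pair in a [behavior_map()].
#' Vectorised; an `NA` on either side yields `NA` (no-data).
#'
#' @param posture Character or factor over lying/sitting/standing.
#' @param activity Character or factor over
#'   inactive/active/highly_active.
#' @param map Matrix from [behavior_map()].
#' @return Character vector of behavior labels.
#' @examples
#' classify_behavior("standing", "active") # "active standing"
#' @export
classify_behavior <- function(posture, activity, map = behavior_map()) {
  posture <- as.character(posture)
  activity <- as.character(activity)
  ok <- !is.na(posture) & !is.na(activity)
  if (any(!posture[ok] %in% POSTURES))
    stop("unknown posture label", call. = FALSE)
  if (any(!activity[ok] %in% ACTIVITY_LEVELS))
    stop("unknown activity label", call. = FALSE)
  out <- rep(NA_character_, length(ok))
  out[ok] <- map[cbind(posture[ok], activity[ok])]
  out
}

#' Sliding-mode smoothing of the posture stream
#'
#' Emits one posture per second: the most frequent label among the
#' detections in the trailing `window_s` window `(t - window_s, t]`.
#' This suppresses single-frame misclassifications. Ties are broken by
#' the larger summed confidence of the tied labels, then by the fixed
#' order lying < sitting < standing; the reported confidence is the
#' maximum confidence among the winning label's votes. Seconds whose
#' window holds no detection are emitted as no-data.
#'
#' @param series A [detection_series()].
#' @param window_s Smoothing window in seconds (default 5).
#' @param duration_s Coverage in seconds; defaults to the stream length
#'   implied by the last frame index.
#' @return Data frame with one row per second: `t`, `posture`
#'   (character, `NA` for no-data), `confidence`.
#' @export
smooth_posture <- function(series, window_s = 5, duration_s = NULL) {
  fps <- attr(series, "fps")
  if (is.null(fps)) fps <- 5
  if (is.null(duration_s))
    duration_s <- if (nrow(series) > 0)
      ceiling((max(series$frame_index) + 1) / fps) else 0
  ts <- seq_len(duration_s)
  if (duration_s == 0)
    return(data.frame(t = numeric(0), posture = character(0),
                      confidence = numeric(0)))
  det <- series[!is.na(series$posture), , drop = FALSE]
  eps <- 1e-9
  rows <- lapply(ts, function(t) {
    lo <- floor(fps * (t - window_s) + eps) + 1
    hi <- floor(fps * t + eps)
    win <- det[det$frame_index >= lo & det$frame_index <= hi, , drop = FALSE]
    if (nrow(win) == 0)
      return(data.frame(t = t, posture = NA_character_,
                        confidence = NA_real_))
    votes <- table(factor(win$posture, levels = POSTURES))
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      conf_sum <- vapply(top, function(p)
        sum(win$confidence[win$posture == p]), 0)
      top <- top[conf_sum == max(conf_sum)]
      top <- top[order(match(top, POSTURES))][1]
    }
    data.frame(t = t, posture = top,
               confidence = max(win$confidence[win$posture == top]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fuse the per-second streams of two opposing cameras
#'
#' Two cameras on opposite sides of the enclosure watch the same
#' animal; each has blind spots (e.g. the legs hidden behind the
#' platform make a standing fox look lying). Per second the fused
#' record takes the larger of the two windowed mean norms, and on
#' posture disagreement the label reported with the higher confidence.
#' If confidences also tie, the camera with the larger mean norm wins,
#' then the fixed posture order. A second covered by only one camera is
#' passed through; a second covered by neither is no-data. Fusion is
#' commutative in its arguments and the identity on identical inputs.
#'
#' @param a,b Per-camera, per-second data frames with columns `t`,
#'   `posture`, `confidence`, `mean_norm` (as produced by joining
#'   [smooth_posture()] and [windowed_mean_norm()] on `t`), plus
#'   optionally `camera_id`.
#' @param tolerance_s Samples from the two cameras are aligned by
#'   nearest timestamp; pairs farther apart than this are not joined
#'   (default 0.5 s).
#' @return Data frame: `t`, `posture`, `confidence`, `mean_norm`,
#'   `source_camera` (`"both"` when the cameras agreed).
#' @export
fuse_cameras <- function(a, b, tolerance_s = 0.5) {
  id_a <- if ("camera_id" %in% names(a) && nrow(a) > 0)
    as.character(a$camera_id[1]) else "cam1"
  id_b <- if ("camera_id" %in% names(b) && nrow(b) > 0)
    as.character(b$camera_id[1]) else "cam2"
  grid <- sort(unique(c(a$t, b$t)))
  ia <- nearest_within(grid, a$t, tolerance_s)
  ib <- nearest_within(grid, b$t, tolerance_s)
  pick <- function(x, idx, col) {
    out <- rep(NA, length(idx))
    ok <- !is.na(idx)
    out[ok] <- x[[col]][idx[ok]]
    out
  }
  pa <- as.character(pick(a, ia, "posture")); ca <- pick(a, ia, "confidence")
  pb <- as.character(pick(b, ib, "posture")); cb <- pick(b, ib, "confidence")
  na_ <- pick(a, ia, "mean_norm"); nb <- pick(b, ib, "mean_norm")
  norm <- pmax(na_, nb, na.rm = TRUE)
  norm[is.na(na_) & is.na(nb)] <- NA_real_
  n <- length(grid)
  posture <- rep(NA_character_, n)
  confidence <- rep(NA_real_, n)
  source <- rep(NA_character_, n)
  only_a <- !is.na(pa) & is.na(pb)
  only_b <- is.na(pa) & !is.na(pb)
  agree <- !is.na(pa) & !is.na(pb) & pa == pb
  differ <- !is.na(pa) & !is.na(pb) & pa != pb
  posture[only_a] <- pa[only_a]; confidence[only_a] <- ca[only_a]
  source[only_a] <- id_a
  posture[only_b] <- pb[only_b]; confidence[only_b] <- cb[only_b]
  source[only_b] <- id_b
  posture[agree] <- pa[agree]
  confidence[agree] <- pmax(ca[agree], cb[agree])
  source[agree] <- "both"
  if (any(differ)) {
    a_wins <- ca[differ] > cb[differ] |
      (ca[differ] == cb[differ] &
         (coalesce0(na_[differ]) > coalesce0(nb[differ]) |
            (coalesce0(na_[differ]) == coalesce0(nb[differ]) &
               match(pa[differ], POSTURES) <= match(pb[differ], POSTURES))))
    posture[differ] <- ifelse(a_wins, pa[differ], pb[differ])
    confidence[differ] <- ifelse(a_wins, ca[differ], cb[differ])
    source[differ] <- ifelse(a_wins, id_a, id_b)
  }
  data.frame(t = grid, posture = posture, confidence = confidence,
             mean_norm = norm, source_camera = source)
}

coalesce0 <- function(x) ifelse(is.na(x), 0, x)

# index of the nearest element of ts for each target, NA beyond tol
nearest_within <- function(targets, ts, tol) {
  if (length(ts) == 0) return(rep(NA_integer_, length(targets)))
  pos <- findInterval(targets, ts)
  lo <- pmax(pos, 1)
  hi <- pmin(pos + 1, length(ts))
  use_hi <- abs(ts[hi] - targets) < abs(ts[lo] - targets)
  idx <- ifelse(use_hi, hi, lo)
  idx[abs(ts[idx] - targets) > tol] <- NA_integer_
  idx
}

#' Count posture changes per time bin
#'
#' A change is a pair of consecutive timeline samples whose (non
#' no-data) posture labels differ; it is counted into the bin of the
#' later sample. A no-data stretch between two samples suppresses the
#' count — the animal may have changed posture any number of times
#' while unobserved. Restlessness shows up directly in these counts.
#'
#' @param timeline Data frame with columns `t` (seconds, 1 Hz) and
#'   `posture` (character, `NA` = no-data), e.g. from
#'   [smooth_posture()] or [fuse_cameras()].
#' @param bin_width_s Bin width in seconds (default 1800 = 30 min);
#'   bins are aligned to multiples of the width from t = 0.
#' @return Data frame: `bin_start`, `bin_end`, `changes`.
#' @export
count_posture_changes <- function(timeline, bin_width_s = 1800) {
  timeline <- timeline[order(timeline$t), , drop = FALSE]
  n <- nrow(timeline)
  bins <- bin_starts(timeline$t, bin_width_s)
  out <- data.frame(bin_start = bins, bin_end = bins + bin_width_s,
                    changes = integer(length(bins)))
  if (n >= 2) {
    p <- timeline$posture
    adjacent <- diff(timeline$t) <= 1 + 1e-9 # no missing second between rows
    chg <- which(adjacent & !is.na(p[-n]) & !is.na(p[-1]) & p[-n] != p[-1]) + 1L
    if (length(chg) > 0) {
      b <- floor((timeline$t[chg] - 1e-9) / bin_width_s) * bin_width_s
      tab <- table(factor(b, levels = bins))
      out$changes <- as.integer(tab)
    }
  }
  out
}

# sample at time t covers the second (t - 1, t]; bin by its end point
bin_starts <- function(t, width) {
  if (length(t) == 0) return(numeric(0))
  lo <- floor((min(t) - 1e-9) / width) * width
  hi <- floor((max(t) - 1e-9) / width) * width
  seq(lo, hi, by = width)
}

#' Per-second behavior timeline
#'
#' Joins a 1 Hz posture stream with a 1 Hz activity stream and applies
#' the behavior decision tree, yielding exactly one behavior (or
#' no-data) per second: the animal never shows two behaviors at once.
#' Seconds where either input is missing are no-data.
#'
#' @param postures Data frame `t`, `posture` (plus extra columns, kept)
#'   — typically [fuse_cameras()] output.
#' @param activities Data frame `t`, `level` from
#'   [windowed_mean_norm()]; may be omitted if `postures` already
#'   carries a `mean_norm` column, in which case levels are derived
#'   from it.
#' @param map Behavior map from [behavior_map()].
#' @param cfg [activity_config()] used when deriving levels from
#'   `mean_norm`.
#' @return Data frame: `t`, `posture`, `level`, `behavior`.
#' @export
behavior_timeline <- function(postures, activities = NULL,
                              map = behavior_map(),
                              cfg = activity_config()) {
  out <- data.frame(t = postures$t, posture = as.character(postures$posture))
  if (is.null(activities)) {
    if (!"mean_norm" %in% names(postures))
      stop("need either an activities table or a mean_norm column",
           call. = FALSE)
    out$level <- classify_activity(postures$mean_norm, cfg)
  } else {
    idx <- nearest_within(out$t, activities$t, 0.5)
    lev <- rep(NA_character_, nrow(out))
    lev[!is.na(idx)] <- as.character(activities$level[idx[!is.na(idx)]])
    out$level <- factor(lev, levels = ACTIVITY_LEVELS)
  }
  out$behavior <- classify_behavior(out$posture, out$level, map)
  out
}

#' Aggregate a behavior timeline into binned overviews
#'
#' Splits the 1 Hz timeline into clock-aligned bins (default 30 min)
#' and tallies, per bin, the seconds spent in each activity level, each
#' posture, and each behavior, plus the posture-change count. Within a
#' bin the per-family seconds each sum to the bin's covered (non
#' no-data) seconds.
#'
#' @param timeline Data frame from [behavior_timeline()].
#' @param bin_width_s Bin width in seconds (default 1800).
#' @param map Behavior map (defines the behavior column set).
#' @return Data frame: `bin_start`, `bin_end`, `covered_s`, one
#'   `posture_*` column per posture, one `activity_*` per level, one
#'   `behavior_*` per behavior label, and `changes`.
#' @export
aggregate_overview <- function(timeline, bin_width_s = 1800,
                               map = behavior_map()) {
  bins <- bin_starts(timeline$t, bin_width_s)
  bin_of <- floor((timeline$t - 1e-9) / bin_width_s) * bin_width_s
  ok <- !is.na(timeline$behavior) # a covered second has all three labels
  fbin <- factor(bin_of[ok], levels = bins)
  tally <- function(values, levels, prefix) {
    tab <- table(fbin, factor(values[ok], levels = levels))
    df <- as.data.frame.matrix(tab)
    names(df) <- paste0(prefix, gsub(" ", "_", names(df)))
    df
  }
  behaviors <- unique(as.vector(map))
  out <- cbind(
    data.frame(bin_start = bins, bin_end = bins + bin_width_s),
    covered_s = as.integer(table(fbin)),
    tally(timeline$posture, POSTURES, "posture_"),
    tally(as.character(timeline$level), ACTIVITY_LEVELS, "activity_"),
    tally(timeline$behavior, behaviors, "behavior_")
  )
  out$changes <- count_posture_changes(timeline, bin_width_s)$changes
  rownames(out) <- NULL
  out
}
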