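#' Per-camera analysis: smoothed posture plus windowed activity
#'
#' Runs the per-camera half of the workflow on one detection series:
#' best-per-frame selection is assumed done, postures are mode-smoothed
#' over a trailing window, and the windowed mean displacement norm is
#' computed on the same 1 Hz grid.
#'
#' @param series A [detection_series()].
#' @param act An [activity_config()].
#' @param window_s Posture smoothing window (default 5 s).
#' @param duration_s Coverage in seconds (defaults to the stream
#'   length).
#' @return Per-second data frame: `t`, `posture`, `confidence`,
#'   `mean_norm`, `level`, `camera_id`.
#' @export
process_camera <- function(series, act = activity_config(), window_s = 5,
                           duration_s = NULL) {
  fps <- attr(series, "fps")
  if (is.null(fps)) fps <- 5
  if (is.null(duration_s))
    duration_s <- if (nrow(series) > 0)
      ceiling((max(series$frame_index) + 1) / fps) else 0
  post <- smooth_posture(series, window_s = window_s,
                         duration_s = duration_s)
  norm <- windowed_mean_norm(displacements(series), cfg = act, fps = fps,
                             duration_s = duration_s)
  out <- merge(post, norm, by = "t", all.x = TRUE)
  out$camera_id <- rep(if (nrow(series) > 0) series$camera_id[1] else "cam",
                       nrow(out))
  out[order(out$t), , drop = FALSE]
}

#' Run the full monitoring pipeline on one or two detection streams
#'
#' End-to-end orchestration of the workflow: per camera, mode-smoothed
#' postures and windowed activity; fusion of the two cameras (a single
#' camera passes through unchanged); behavior classification on the
#' fused 1 Hz stream; binned overview aggregation. Optionally writes
#' the per-second timeline, the overview table, a JSON summary and a
#' manifest (configuration echo) to `out_dir`.
#'
#' @param streams A named list of one or two [detection_series()] (e.g.
#'   from [read_detections()] or [make_fixture()]), or a character
#'   vector of stream file paths.
#' @param act An [activity_config()].
#' @param map Behavior map from [behavior_map()].
#' @param window_s Posture smoothing window in seconds.
#' @param bin_width_s Overview bin width in seconds (default 1800).
#' @param tolerance_s Camera-alignment tolerance for fusion.
#' @param fps Frames per second, used when reading streams from paths.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return A list of class `fox_report`: `per_camera`, `fused`,
#'   `timeline`, `overview`, `summary`, and `paths` when written.
#' @export
run_pipeline <- function(streams, act = activity_config(),
                         map = behavior_map(), window_s = 5,
                         bin_width_s = 1800, tolerance_s = 0.5,
                         fps = 5, out_dir = NULL) {
  if (is.character(streams)) {
    streams <- do.call(c, lapply(streams, read_detections, fps = fps))
  }
  if (is.data.frame(streams)) streams <- list(streams)
  if (length(streams) < 1 || length(streams) > 2)
    stop("expected one or two detection streams", call. = FALSE)
  fps_seen <- unique(vapply(streams, function(s) {
    f <- attr(s, "fps"); if (is.null(f)) fps else f
  }, 0))
  if (length(fps_seen) > 1)
    stop("streams disagree on fps: ", paste(fps_seen, collapse = " vs "),
         call. = FALSE)
  if (all(vapply(streams, nrow, 0L) == 0))
    warning("empty detection streams; reports will be empty", call. = FALSE)
  duration_s <- max(c(0, vapply(streams, function(s)
    if (nrow(s) > 0) ceiling((max(s$frame_index) + 1) / fps_seen[1]) else 0,
    0)))
  per_camera <- lapply(streams, process_camera, act = act,
                       window_s = window_s, duration_s = duration_s)
  fused <- if (length(per_camera) == 2)
    fuse_cameras(per_camera[[1]], per_camera[[2]],
                 tolerance_s = tolerance_s)
  else per_camera[[1]]
  timeline <- behavior_timeline(fused, map = map, cfg = act)
  timeline$mean_norm <- fused$mean_norm[match(timeline$t, fused$t)]
  overview <- aggregate_overview(timeline, bin_width_s = bin_width_s,
                                 map = map)
  covered <- sum(!is.na(timeline$behavior))
  summary <- list(
    duration_s = duration_s,
    covered_s = covered,
    coverage = if (duration_s > 0) covered / duration_s else NA_real_,
    posture_changes = sum(overview$changes),
    seconds_per_behavior = as.list(colSums(
      overview[grep("^behavior_", names(overview))])),
    seconds_per_level = as.list(colSums(
      overview[grep("^activity_", names(overview))])),
    seconds_per_posture = as.list(colSums(
      overview[grep("^posture_", names(overview))]))
  )
  report <- list(per_camera = per_camera, fused = fused,
                 timeline = timeline, overview = overview,
                 summary = summary)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(timeline = file.path(out_dir, "timeline.csv"),
                  overview = file.path(out_dir, "overview.csv"),
                  summary = file.path(out_dir, "summary.json"),
                  manifest = file.path(out_dir, "manifest.json"))
    utils::write.csv(timeline, paths$timeline, row.names = FALSE)
    utils::write.csv(overview, paths$overview, row.names = FALSE)
    jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                         digits = NA)
    manifest <- list(
      package = "foxwatch",
      version = as.character(utils::packageVersion("foxwatch")),
      fps = fps_seen[1], window_s = window_s, bin_width_s = bin_width_s,
      tolerance_s = tolerance_s, activity = unclass(act),
      behaviors = unique(as.vector(map)),
      cameras = names(streams))
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA)
    report$paths <- paths
  }
  structure(report, class = "fox_report")
}

#' @export
print.fox_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("fox monitoring report: %d s analysed, %d s covered (%.1f%%)\n",
              s$duration_s, s$covered_s, 100 * s$coverage))
  cat(sprintf("posture changes: %d\n", s$posture_changes))
  cat("time budget (s):\n")
  for (b in names(s$seconds_per_behavior))
    cat(sprintf("  %-30s %6d\n", sub("^behavior_", "", b),
                s$seconds_per_behavior[[b]]))
  invisible(x)
}
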