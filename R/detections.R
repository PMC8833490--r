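DETECTION_COLUMNS <- c(
  "camera_id", "frame_index", "timestamp", "posture", "confidence",
  "cx", "cy", "w", "h"
)

#' Construct a per-camera detection series
#'
#' A detection series is one camera's stream of per-frame detector
#' output: at most one record per sampled frame, ordered by time.
#' Frames where the detector saw nothing are kept as explicit gap
#' records (`NA` posture, confidence and box) rather than dropped,
#' because downstream windowing must know which frames are missing.
#'
#' @param records Data frame with columns `frame_index`, `posture`,
#'   `confidence`, `cx`, `cy`, `w`, `h` and optionally `timestamp`
#'   (filled in as `frame_index / fps` when absent) and `camera_id`.
#' @param fps Sampling rate of the stream in frames per second
#'   (default 5, the rate used for enclosure monitoring).
#' @param camera_id Camera identifier; overrides any `camera_id` column.
#' @return A data frame of class `detection_series`, sorted by
#'   `frame_index`, with attribute `fps`.
#' @export
detection_series <- function(records, fps = 5, camera_id = NULL) {
  stopifnot(is.data.frame(records), fps > 0)
  if (is.null(camera_id)) {
    camera_id <- if ("camera_id" %in% names(records) && nrow(records) > 0)
      as.character(records$camera_id[1]) else "cam"
  }
  records$camera_id <- rep(as.character(camera_id), nrow(records))
  if (!"timestamp" %in% names(records) || all(is.na(records$timestamp)))
    records$timestamp <- records$frame_index / fps
  for (col in setdiff(DETECTION_COLUMNS, names(records)))
    records[[col]] <- rep(NA, nrow(records))
  records <- records[DETECTION_COLUMNS]
  records <- records[order(records$frame_index), , drop = FALSE]
  rownames(records) <- NULL
  validate_detection_records(records)
  if (anyDuplicated(records$frame_index))
    stop("duplicate frame_index in series; run best_detection_per_frame() first",
         call. = FALSE)
  if (nrow(records) > 1 && any(diff(records$timestamp) <= 0))
    stop("timestamps are not strictly increasing", call. = FALSE)
  structure(records, fps = fps, class = c("detection_series", "data.frame"))
}

validate_detection_records <- function(records, lines = NULL) {
  report <- function(rows, msg) {
    loc <- if (is.null(lines)) paste("row", rows) else paste("line", lines[rows])
    stop(sprintf("%s (%s)", msg, paste(utils::head(loc, 5), collapse = ", ")),
         call. = FALSE)
  }
  det <- !is.na(records$posture)
  bad <- det & !(records$posture %in% POSTURES)
  if (any(bad)) report(which(bad), "unknown posture label")
  bad <- det & (is.na(records$confidence) | records$confidence < 0 |
                  records$confidence > 1)
  if (any(bad)) report(which(bad), "confidence outside [0, 1]")
  box <- records[c("cx", "cy", "w", "h")]
  bad <- det & (is.na(box$cx) | is.na(box$cy) | is.na(box$w) | is.na(box$h))
  if (any(bad)) report(which(bad), "detection without a complete bounding box")
  if (any(det)) {
    b <- box[det, , drop = FALSE]
    ok <- b$cx >= 0 & b$cx <= 1 & b$cy >= 0 & b$cy <= 1 &
      b$w > 0 & b$w <= 1 & b$h > 0 & b$h <= 1
    if (any(!ok)) report(which(det)[!ok], "bounding box outside normalized range")
  }
  invisible(records)
}

#' Keep the best detection in every frame
#'
#' Detectors can emit several boxes for a frame even though a single
#' animal is in view. Per frame the detection with maximal confidence is
#' kept; ties are broken by larger box area, then by the fixed posture
#' order lying < sitting < standing, so the result is deterministic and
#' independent of input order.
#'
#' @param records Data frame of raw detections (possibly several per
#'   `frame_index`); same columns as [detection_series()].
#' @param fps,camera_id Passed to [detection_series()].
#' @param n_frames Optional total frame count; frames in
#'   `0:(n_frames - 1)` with no detection become explicit gap records.
#' @return A [detection_series()] with at most one record per frame.
#' @export
best_detection_per_frame <- function(records, fps = 5, camera_id = NULL,
                                     n_frames = NULL) {
  stopifnot(is.data.frame(records))
  if (nrow(records) > 0) {
    det <- records[!is.na(records$posture), , drop = FALSE]
    area <- det$w * det$h
    rank <- order(det$frame_index, -det$confidence, -area,
                  match(det$posture, POSTURES))
    det <- det[rank, , drop = FALSE]
    det <- det[!duplicated(det$frame_index), , drop = FALSE]
  } else det <- records
  if (!is.null(n_frames)) {
    missing_idx <- setdiff(seq_len(n_frames) - 1L, det$frame_index)
    if (length(missing_idx) > 0) {
      gaps <- data.frame(frame_index = missing_idx, posture = NA_character_,
                         confidence = NA_real_, cx = NA_real_, cy = NA_real_,
                         w = NA_real_, h = NA_real_)
      keep <- intersect(names(det), names(gaps))
      det <- rbind(det[names(gaps)], gaps)
    }
  }
  if ("timestamp" %in% names(det)) det$timestamp <- NULL
  detection_series(det, fps = fps, camera_id = camera_id)
}

#' Frame indices realising a target sampling rate
#'
#' Maps a target rate onto a native video rate by index arithmetic:
#' indices `round(k * native_fps / target_fps)` for `k = 0, 1, ...`,
#' deduplicated and restricted to `[0, n_frames)`. No video is touched;
#' this is pure arithmetic so that upstream frame extraction and this
#' pipeline agree on which frames are meant.
#'
#' @param native_fps Recording rate of the source video (e.g. 15).
#' @param target_fps Desired analysis rate (e.g. 5); must not exceed
#'   `native_fps`.
#' @param n_frames Number of frames in the source video.
#' @return Integer vector of 0-based frame indices.
#' @examples
#' sample_frame_indices(15, 5, 9) # 0 3 6
#' @export
sample_frame_indices <- function(native_fps, target_fps, n_frames) {
  stopifnot(native_fps > 0, n_frames >= 0)
  if (target_fps <= 0 || target_fps > native_fps)
    stop("target_fps must lie in (0, native_fps]", call. = FALSE)
  if (n_frames == 0) return(integer(0))
  k <- 0:ceiling((n_frames - 1) * target_fps / native_fps)
  idx <- unique(as.integer(round(k * native_fps / target_fps)))
  idx[idx < n_frames]
}
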