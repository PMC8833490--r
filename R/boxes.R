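#' Posture, activity and behavior label constants
#'
#' The pipeline recognises exactly three postures (`lying`, `sitting`,
#' `standing`) and three activity levels (`inactive`, `active`,
#' `highly_active`). The fixed order of `POSTURES` doubles as the
#' deterministic tie-break order used throughout the package.
#'
#' @format Character vectors.
#' @name labels
NULL

#' @rdname labels
#' @export
POSTURES <- c("lying", "sitting", "standing")

#' @rdname labels
#' @export
ACTIVITY_LEVELS <- c("inactive", "active", "highly_active")

#' Construct a normalized center-format bounding box
#'
#' Boxes follow the YOLO convention: center `(cx, cy)` plus width and
#' height, all expressed as fractions of image width/height. The center
#' must lie inside the unit square and width/height must be positive and
#' at most 1; corner extents beyond the image are clamped when areas are
#' computed.
#'
#' @param cx,cy Box center, fractions of image width/height in `[0, 1]`.
#' @param w,h Box width and height, fractions in `(0, 1]`. Vectors are
#'   recycled to a common length.
#' @return A data frame with columns `cx`, `cy`, `w`, `h`.
#' @examples
#' bbox(0.5, 0.5, 0.2, 0.2)
#' @export
bbox <- function(cx, cy, w, h) {
  box <- data.frame(cx = cx, cy = cy, w = w, h = h)
  validate_boxes(box)
  box
}

validate_boxes <- function(box, where = "box") {
  bad <- function(msg) stop(sprintf("invalid %s: %s", where, msg), call. = FALSE)
  for (col in c("cx", "cy", "w", "h")) {
    if (!col %in% names(box)) bad(sprintf("missing field '%s'", col))
    if (!is.numeric(box[[col]])) bad(sprintf("field '%s' is not numeric", col))
  }
  if (any(!is.finite(as.matrix(box[c("cx", "cy", "w", "h")]))))
    bad("non-finite coordinate")
  if (any(box$cx < 0 | box$cx > 1 | box$cy < 0 | box$cy > 1))
    bad("center outside [0, 1]")
  if (any(box$w <= 0 | box$w > 1 | box$h <= 0 | box$h > 1))
    bad("width/height outside (0, 1]")
  invisible(box)
}

# corner representation, clamped to the unit square
box_corners <- function(box) {
  data.frame(
    xmin = pmax(box$cx - box$w / 2, 0),
    xmax = pmin(box$cx + box$w / 2, 1),
    ymin = pmax(box$cy - box$h / 2, 0),
    ymax = pmin(box$cy + box$h / 2, 1)
  )
}

#' Intersection over union of two bounding boxes
#'
#' Overlap area divided by union area, computed on the clamped corner
#' representation in normalized units. Vectorised over rows; the two
#' inputs are recycled to a common length. Degenerate zero-area boxes
#' (possible after clamping a box whose center sits on the image edge)
#' yield an IoU of 0 rather than an error, so that malformed predictions
#' are scored as misses during matching instead of aborting a run.
#'
#' @param a,b Data frames of boxes as returned by [bbox()].
#' @return Numeric vector of IoU values in `[0, 1]`.
#' @examples
#' box_iou(bbox(0.5, 0.5, 0.2, 0.2), bbox(0.55, 0.5, 0.2, 0.2)) # 0.6
#' @export
box_iou <- function(a, b) {
  ca <- box_corners(a)
  cb <- box_corners(b)
  iw <- pmax(0, pmin(ca$xmax, cb$xmax) - pmax(ca$xmin, cb$xmin))
  ih <- pmax(0, pmin(ca$ymax, cb$ymax) - pmax(ca$ymin, cb$ymin))
  inter <- iw * ih
  area_a <- (ca$xmax - ca$xmin) * (ca$ymax - ca$ymin)
  area_b <- (cb$xmax - cb$xmin) * (cb$ymax - cb$ymin)
  union <- area_a + area_b - inter
  ifelse(union > 0, inter / union, 0)
}
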