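# Independent oracles for the evaluation metrics. These deliberately
# share no code with the package: the AP oracle enumerates every PR
# point explicitly and maximises over the recall grid by looping, and
# the IoU oracle rasterizes both boxes on an n x n pixel grid and
# counts cells.

oracle_ap <- function(is_tp, n_truths) {
  stopifnot(n_truths >= 1)
  pr_points <- list()
  tp <- 0
  for (k in seq_along(is_tp)) {
    if (is_tp[k]) tp <- tp + 1
    pr_points[[k]] <- c(recall = tp / n_truths, precision = tp / k)
  }
  total <- 0
  for (r in (0:10) / 10) {
    best <- 0
    for (pt in pr_points)
      if (pt[["recall"]] >= r - 1e-12 && pt[["precision"]] > best)
        best <- pt[["precision"]]
    total <- total + best
  }
  total / 11
}

# cells of an n x n grid whose centers fall inside the clamped box;
# per-axis index range [ceil(n*lo + 1/2), floor(n*hi + 1/2)]
raster_range <- function(lo, hi, n) {
  lo <- max(lo, 0); hi <- min(hi, 1)
  i0 <- ceiling(n * lo + 0.5)
  i1 <- floor(n * hi + 0.5)
  c(i0, i1)
}

oracle_iou_raster <- function(a, b, n = 2000) {
  count <- function(box) {
    rx <- raster_range(box$cx - box$w / 2, box$cx + box$w / 2, n)
    ry <- raster_range(box$cy - box$h / 2, box$cy + box$h / 2, n)
    max(0, rx[2] - rx[1] + 1) * max(0, ry[2] - ry[1] + 1)
  }
  inter_count <- function(a, b) {
    ax <- raster_range(a$cx - a$w / 2, a$cx + a$w / 2, n)
    bx <- raster_range(b$cx - b$w / 2, b$cx + b$w / 2, n)
    ay <- raster_range(a$cy - a$h / 2, a$cy + a$h / 2, n)
    by <- raster_range(b$cy - b$h / 2, b$cy + b$h / 2, n)
    max(0, min(ax[2], bx[2]) - max(ax[1], bx[1]) + 1) *
      max(0, min(ay[2], by[2]) - max(ay[1], by[1]) + 1)
  }
  i <- inter_count(a, b)
  u <- count(a) + count(b) - i
  if (u > 0) i / u else 0
}

# random annotation-like box: pixel-aligned on a 2000 px grid (real
# labels are pixel-aligned), extents at least 5% of the frame per axis
# as a fox never occupies fewer pixels in this footage
random_box <- function(n = 2000) {
  w <- sample(floor(0.05 * n):floor(0.6 * n), 1)
  h <- sample(floor(0.05 * n):floor(0.6 * n), 1)
  x0 <- sample(0:(n - w), 1)
  y0 <- sample(0:(n - h), 1)
  bbox((x0 + w / 2) / n, (y0 + h / 2) / n, w / n, h / n)
}

# detection series with constant center and a scripted posture
# schedule: switch_times[i] is the second at which posture becomes
# schedule[i + 1]
scripted_series <- function(duration_s, schedule, switch_times, fps = 5,
                            camera_id = "cam1") {
  n <- duration_s * fps
  tt <- (seq_len(n) - 1) / fps
  seg <- findInterval(tt, c(0, switch_times))
  detection_series(data.frame(
    frame_index = seq_len(n) - 1L, posture = schedule[seg],
    confidence = 0.9, cx = 0.5, cy = 0.5, w = 0.2, h = 0.2),
    fps = fps, camera_id = camera_id)
}
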