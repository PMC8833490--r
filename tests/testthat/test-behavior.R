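per_second <- function(t, posture, confidence = 0.9, mean_norm = 0.001,
                       camera_id = "cam1") {
  data.frame(t = t, posture = posture, confidence = confidence,
             mean_norm = mean_norm, camera_id = camera_id)
}

test_that("the default decision tree yields the 7-label ethogram", {
  map <- behavior_map()
  expect_equal(length(unique(as.vector(map))), 7)
  expect_equal(classify_behavior("standing", "active", map), "active standing")
  expect_equal(classify_behavior("lying", "inactive", map), "lying motionless")
  expect_equal(classify_behavior("lying", "highly_active", map), "active lying")
  strict <- behavior_map(strict_nine = TRUE)
  expect_equal(length(unique(as.vector(strict))), 9)
  expect_equal(classify_behavior("lying", "highly_active", strict),
               "highly active lying")
})

test_that("behavior classification is total on its domain and NA-safe", {
  grid <- expand.grid(posture = POSTURES, activity = ACTIVITY_LEVELS,
                      stringsAsFactors = FALSE)
  out <- classify_behavior(grid$posture, grid$activity)
  expect_false(any(is.na(out)))
  expect_error(classify_behavior("crouching", "active"), "unknown posture")
  expect_error(classify_behavior("lying", "frantic"), "unknown activity")
  expect_true(is.na(classify_behavior(NA, "active")))
})

test_that("mode smoothing removes isolated flips and keeps constants", {
  n <- 50
  rec <- data.frame(frame_index = 0:(n - 1), posture = "sitting",
                    confidence = 0.9, cx = 0.5, cy = 0.5, w = 0.2, h = 0.2)
  rec$posture[12] <- "standing" # 1 flipped frame inside every window
  s <- detection_series(rec, fps = 5)
  sm <- smooth_posture(s)
  expect_true(all(sm$posture == "sitting"))
  rec$posture <- "lying"
  expect_true(all(smooth_posture(detection_series(rec, fps = 5))$posture ==
                    "lying"))
})

test_that("smoothing ties go to the larger summed confidence", {
  rec <- data.frame(frame_index = 0:3,
                    posture = c("sitting", "sitting", "standing", "standing"),
                    confidence = c(0.9, 0.9, 0.6, 0.6),
                    cx = 0.5, cy = 0.5, w = 0.2, h = 0.2)
  sm <- smooth_posture(detection_series(rec, fps = 5), duration_s = 1)
  expect_equal(sm$posture, "sitting")
  expect_equal(sm$confidence, 0.9)
})

test_that("smoothing emits no-data on empty windows, never foreign labels", {
  rec <- data.frame(frame_index = 0:49, posture = NA_character_,
                    confidence = NA_real_, cx = NA_real_, cy = NA_real_,
                    w = NA_real_, h = NA_real_)
  rec[1:10, ] <- data.frame(frame_index = 0:9, posture = "lying",
                            confidence = 0.8, cx = 0.5, cy = 0.5,
                            w = 0.3, h = 0.12)
  sm <- smooth_posture(detection_series(rec, fps = 5))
  expect_true(all(is.na(sm$posture[sm$t >= 8])))
  expect_true(all(sm$posture[!is.na(sm$posture)] == "lying"))
})

test_that("fusion takes the larger norm and the higher-confidence posture", {
  a <- per_second(1:3, "lying", 0.80, c(0.002, 0.011, 0.003), "cam1")
  b <- per_second(1:3, "standing", 0.95, c(0.011, 0.002, 0.003), "cam2")
  f <- fuse_cameras(a, b)
  expect_true(all(f$posture == "standing")) # blind-spot case
  expect_true(all(f$mean_norm == c(0.011, 0.011, 0.003)))
  expect_equal(f$source_camera, rep("cam2", 3))
})

test_that("fusion is commutative and the identity on agreement", {
  a <- per_second(1:5, c("lying", "lying", "sitting", "standing", "lying"),
                  runif(5, 0.6, 1), runif(5, 0, 0.01), "cam1")
  b <- per_second(1:5, c("standing", "lying", "sitting", "lying", "lying"),
                  runif(5, 0.6, 1), runif(5, 0, 0.01), "cam2")
  f_ab <- fuse_cameras(a, b)
  f_ba <- fuse_cameras(b, a)
  expect_equal(f_ab$posture, f_ba$posture)
  expect_equal(f_ab$mean_norm, f_ba$mean_norm)
  expect_equal(f_ab$confidence, f_ba$confidence)
  same <- fuse_cameras(a, a)
  expect_equal(same$posture, a$posture)
  expect_equal(same$mean_norm, a$mean_norm)
  expect_equal(same$confidence, a$confidence)
})

test_that("a second seen by one camera passes through; by neither is no-data", {
  a <- per_second(1:2, c("sitting", NA), c(0.9, NA), c(0.001, NA))
  b <- per_second(1:2, c(NA, NA), c(NA, NA), c(NA, NA), "cam2")
  f <- fuse_cameras(a, b)
  expect_equal(f$posture, c("sitting", NA))
  expect_equal(f$source_camera, c("cam1", NA))
})

test_that("posture changes are counted per bin and gaps suppress them", {
  tl <- data.frame(t = 1:4,
                   posture = c("lying", "sitting", "standing", "sitting"))
  expect_equal(sum(count_posture_changes(tl)$changes), 3)
  const <- data.frame(t = 1:1800, posture = "lying")
  expect_equal(count_posture_changes(const)$changes, 0L)
  gap <- data.frame(t = 1:3, posture = c("sitting", NA, "standing"))
  expect_equal(sum(count_posture_changes(gap)$changes), 0)
})

test_that("change counts are shift-invariant and bins sum to the total", {
  set.seed(9)
  tl <- data.frame(t = 1:3600,
                   posture = sample(POSTURES, 3600, TRUE, c(0.9, 0.05, 0.05)))
  total <- sum(count_posture_changes(tl, 600)$changes)
  shifted <- transform(tl, t = t + 7200)
  expect_equal(sum(count_posture_changes(shifted, 600)$changes), total)
  expect_equal(sum(count_posture_changes(tl, 1800)$changes), total)
  p <- tl$posture
  expect_equal(total, sum(p[-1] != p[-3600]))
})

test_that("the behavior timeline emits one sample per covered second", {
  fused <- per_second(1:60, "lying", 0.9, 0.001)
  fused$mean_norm[c(20:22, 40:42)] <- 0.007 # two short active blips
  tl <- behavior_timeline(fused)
  expect_equal(nrow(tl), 60)
  expect_equal(sum(tl$behavior == "active lying"), 6)
  expect_true(all(tl$behavior[-c(20:22, 40:42)] == "lying motionless"))
  expect_equal(nrow(behavior_timeline(fused[0, ])), 0)
})

test_that("overview bins conserve covered seconds across label families", {
  fused <- per_second(1:3600, "sitting", 0.9, 0.001)
  tl <- behavior_timeline(fused)
  ov <- aggregate_overview(tl)
  expect_equal(nrow(ov), 2)
  expect_equal(ov$posture_sitting, c(1800L, 1800L))
  expect_equal(ov$activity_inactive, c(1800L, 1800L))
  expect_equal(ov$behavior_sitting_still, c(1800L, 1800L))
  expect_equal(ov$changes, c(0L, 0L))
  # conservation on a noisy fixture with no-data stretches
  set.seed(14)
  fused2 <- per_second(1:2000, sample(c(POSTURES, NA), 2000, TRUE),
                       0.9, runif(2000, 0, 0.02))
  tl2 <- behavior_timeline(fused2)
  ov2 <- aggregate_overview(tl2, 600)
  post <- rowSums(ov2[grep("^posture_", names(ov2))])
  act <- rowSums(ov2[grep("^activity_", names(ov2))])
  beh <- rowSums(ov2[grep("^behavior_", names(ov2))])
  expect_equal(post, ov2$covered_s)
  expect_equal(act, ov2$covered_s)
  expect_equal(beh, ov2$covered_s)
})
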