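label_set <- function(df) {
  structure(df, image_ids = unique(df$image_id),
            class_names = sort(unique(df$posture)))
}

test_that("IoU handles identity, disjoint and the worked overlap case", {
  A <- bbox(0.5, 0.5, 0.2, 0.2)
  expect_equal(box_iou(A, A), 1)
  expect_equal(box_iou(A, bbox(0.9, 0.9, 0.1, 0.1)), 0)
  # half-width shift: intersection 0.15 x 0.2, union 2*0.04 - 0.03
  expect_equal(box_iou(A, bbox(0.55, 0.5, 0.2, 0.2)), 0.6)
})

test_that("IoU is symmetric, bounded and agrees with a raster oracle", {
  set.seed(10)
  for (i in 1:50) {
    a <- random_box(); b <- random_box()
    v <- box_iou(a, b)
    expect_equal(v, box_iou(b, a))
    expect_true(v >= 0 && v <= 1)
    expect_lt(abs(v - oracle_iou_raster(a, b)), 1e-3)
  }
})

test_that("matching follows the VOC greedy one-to-one contract", {
  gt <- label_set(data.frame(image_id = "i1", posture = "sitting",
                             cx = 0.5, cy = 0.5, w = 0.2, h = 0.2))
  exact <- data.frame(image_id = "i1", posture = "sitting", confidence = 0.9,
                      cx = 0.5, cy = 0.5, w = 0.2, h = 0.2)
  m <- match_detections(exact, gt)
  expect_equal(unlist(m$counts[c("tp", "fp", "fn")]), c(tp = 1, fp = 0, fn = 0))
  expect_equal(m$outcomes$iou, 1)

  # a labeled image with no detections is all false negatives
  m <- match_detections(exact[0, ], gt)
  expect_equal(sum(m$counts$fn), 1)

  # IoU below threshold: the prediction is FP and the truth stays FN
  off <- transform(exact, cx = 0.62) # IoU ~ 0.39
  expect_lt(box_iou(off, gt), 0.5)
  m <- match_detections(off, gt)
  expect_equal(unlist(m$counts[c("tp", "fp", "fn")]), c(tp = 1 - 1, fp = 1, fn = 1))

  # IoU exactly at the threshold counts as TP (>=, not >)
  at <- transform(exact, cx = 0.55)
  thr <- box_iou(at, gt)
  m <- match_detections(at, gt, iou_threshold = thr)
  expect_equal(m$counts$tp, 1)

  # class disagreement is never a match
  wrong <- transform(exact, posture = "standing")
  m <- match_detections(wrong, gt)
  expect_equal(m$counts$fn[m$counts$class == "sitting"], 1)
  expect_equal(m$counts$fp[m$counts$class == "standing"], 1)

  expect_error(match_detections(transform(exact, image_id = "nope"), gt),
               "unlabeled")
})

test_that("TP + FN equals the ground-truth count per class on random instances", {
  set.seed(21)
  for (rep in 1:40) {
    n_gt <- sample(1:5, 1)
    gt <- do.call(rbind, lapply(seq_len(n_gt), function(i)
      cbind(data.frame(image_id = sample(c("a", "b"), 1),
                       posture = sample(POSTURES, 1)), random_box())))
    n_p <- sample(0:6, 1)
    preds <- if (n_p > 0) do.call(rbind, lapply(seq_len(n_p), function(i)
      cbind(data.frame(image_id = sample(c("a", "b"), 1),
                       posture = sample(POSTURES, 1),
                       confidence = runif(1)), random_box()))) else
      data.frame(image_id = character(0), posture = character(0),
                 confidence = numeric(0), cx = numeric(0), cy = numeric(0),
                 w = numeric(0), h = numeric(0))
    gt <- structure(gt, image_ids = c("a", "b"))
    counts <- match_detections(preds, gt)$counts
    for (cl in counts$class) {
      cc <- counts[counts$class == cl, ]
      expect_equal(cc$tp + cc$fn, sum(gt$posture == cl))
    }
  }
})

test_that("precision and recall follow their defining ratios", {
  expect_equal(precision_recall(2, 1, 0),
               list(precision = 2 / 3, recall = 1))
  deg <- precision_recall(0, 0, 5)
  expect_true(is.na(deg$precision))
  expect_equal(deg$recall, 0)
  expect_equal(precision_recall(7, 0, 0), list(precision = 1, recall = 1))
})

test_that("11-point AP matches hand-derived and degenerate cases", {
  expect_equal(interpolated_ap(rep(TRUE, 4), 4), 1)
  expect_equal(interpolated_ap(c(FALSE, FALSE), 3), 0)
  # ranked TP, FP, TP over two truths: 6 grid points at precision 1,
  # five at 2/3
  expect_equal(interpolated_ap(c(TRUE, FALSE, TRUE), 2),
               (6 * 1 + 5 * (2 / 3)) / 11)
  expect_equal(interpolated_ap(c(TRUE, FALSE, TRUE), 2), 28 / 33)
  expect_error(interpolated_ap(c(TRUE), 0), "undefined")
})

test_that("AP is monotone under helpful and harmful additions", {
  set.seed(33)
  for (rep in 1:30) {
    n_truths <- sample(2:5, 1)
    n <- sample(1:6, 1)
    outcomes <- runif(n) < 0.5
    while (sum(outcomes) >= n_truths) outcomes[sample(n, 1)] <- FALSE
    base <- interpolated_ap(outcomes, n_truths)
    # an extra TP for an uncovered truth (appended at lowest rank)
    expect_gte(interpolated_ap(c(outcomes, TRUE), n_truths), base)
    # an extra lowest-ranked FP
    expect_lte(interpolated_ap(c(outcomes, FALSE), n_truths), base)
  }
})

test_that("evaluate composes per-class AP, pooled counts and mean IoU", {
  set.seed(55)
  gt <- do.call(rbind, lapply(1:9, function(i)
    cbind(data.frame(image_id = paste0("img", i),
                     posture = POSTURES[(i - 1) %% 3 + 1]), random_box())))
  perfect <- cbind(gt, confidence = runif(9, 0.6, 1))
  res <- evaluate_detections(perfect, label_set(gt))
  expect_equal(res$mAP, 1)
  expect_equal(res$precision, 1)
  expect_equal(res$recall, 1)
  expect_equal(res$avg_iou, 1)
  expect_equal(res$n_classes, 3)

  # one class perfect, one with no TPs: mAP is the plain mean over classes
  gt2 <- label_set(data.frame(image_id = c("a", "b"),
                              posture = c("lying", "sitting"),
                              cx = 0.5, cy = 0.5, w = 0.2, h = 0.2))
  preds2 <- data.frame(image_id = c("a", "b"),
                       posture = c("lying", "sitting"),
                       confidence = c(0.9, 0.8),
                       cx = c(0.5, 0.9), cy = c(0.5, 0.9),
                       w = 0.2, h = c(0.2, 0.1))
  res2 <- evaluate_detections(preds2, gt2)
  expect_equal(res2$per_class$ap, c(1, 0))
  expect_equal(res2$mAP, 0.5)
})

test_that("evaluation of a corrupted 50-image fixture matches the AP oracle", {
  set.seed(77)
  gt <- do.call(rbind, lapply(1:50, function(i)
    cbind(data.frame(image_id = sprintf("img%02d", i),
                     posture = POSTURES[(i - 1) %% 3 + 1]), random_box())))
  preds <- cbind(gt, confidence = runif(50, 0.5, 1))
  # displace 10% of the boxes far enough to fall below the IoU threshold
  bad <- sample(50, 5)
  preds$cx[bad] <- pmin(1, pmax(0, preds$cx[bad] + 0.9 * preds$w[bad]))
  truths <- label_set(gt)
  res <- evaluate_detections(preds, truths)
  m <- match_detections(preds, truths)
  for (cl in POSTURES) {
    out <- m$outcomes[m$outcomes$class == cl, ]
    expect_equal(res$per_class$ap[res$per_class$class == cl],
                 oracle_ap(out$is_tp, sum(gt$posture == cl)))
  }
  expect_equal(res$mAP, mean(res$per_class$ap))
  expect_equal(res$recall, sum(m$counts$tp) / 50)
})
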