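#' Match predictions to ground truth boxes
#'
#' Greedy one-to-one matching in the Pascal-VOC style: within each
#' image, predictions are processed in order of decreasing confidence
#' (stable sort, so tied confidences keep input order); a prediction is
#' a true positive iff an unmatched ground-truth box of the same class
#' overlaps it with IoU at or above `iou_threshold` (the best-IoU such
#' box is consumed), otherwise a false positive. Ground-truth boxes left
#' unmatched are false negatives — in particular a labeled image on
#' which nothing was detected contributes one false negative per box.
#'
#' @param preds Data frame of predictions: `image_id`, `posture`,
#'   `confidence`, `cx`, `cy`, `w`, `h`.
#' @param truths Label set from [read_yolo_labels()],
#'   [read_voc_labels()], or an equivalent data frame; every `image_id`
#'   in `preds` must be annotated (present in the label set).
#' @param iou_threshold TP threshold on IoU; 0.5 by default, and an IoU
#'   of exactly 0.5 counts as a true positive.
#' @return A list with `counts` (per class: `tp`, `fp`, `fn`) and
#'   `outcomes` (per prediction: class, confidence, `is_tp`, matched
#'   `iou` or `NA`), the latter sorted by decreasing confidence within
#'   class.
#' @export
match_detections <- function(preds, truths, iou_threshold = 0.5) {
  stopifnot(iou_threshold > 0, iou_threshold < 1)
  truth_ids <- attr(truths, "image_ids")
  if (is.null(truth_ids)) truth_ids <- unique(truths$image_id)
  if (nrow(preds) > 0) {
    unknown <- setdiff(unique(preds$image_id), truth_ids)
    if (length(unknown) > 0)
      stop("predictions for unlabeled image(s): ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  classes <- sort(unique(c(truths$posture, preds$posture)))
  truths$matched <- FALSE
  outcomes <- list()
  for (img in unique(preds$image_id)) {
    p <- preds[preds$image_id == img, , drop = FALSE]
    p <- p[order(-p$confidence), , drop = FALSE] # stable: ties keep input order
    t_img <- which(truths$image_id == img)
    for (i in seq_len(nrow(p))) {
      cand <- t_img[truths$posture[t_img] == p$posture[i] &
                      !truths$matched[t_img]]
      iou_i <- NA_real_
      is_tp <- FALSE
      if (length(cand) > 0) {
        ious <- box_iou(p[i, ], truths[cand, , drop = FALSE])
        best <- which.max(ious)
        if (ious[best] >= iou_threshold) {
          truths$matched[cand[best]] <- TRUE
          is_tp <- TRUE
          iou_i <- ious[best]
        }
      }
      outcomes[[length(outcomes) + 1]] <- data.frame(
        class = p$posture[i], confidence = p$confidence[i],
        is_tp = is_tp, iou = iou_i)
    }
  }
  outcomes <- if (length(outcomes) > 0) do.call(rbind, outcomes) else
    data.frame(class = character(0), confidence = numeric(0),
               is_tp = logical(0), iou = numeric(0))
  ord <- order(match(outcomes$class, classes), -outcomes$confidence)
  outcomes <- outcomes[ord, , drop = FALSE]
  rownames(outcomes) <- NULL
  counts <- data.frame(
    class = classes,
    tp = vapply(classes, function(cl)
      sum(outcomes$is_tp[outcomes$class == cl]), 0),
    fp = vapply(classes, function(cl)
      sum(!outcomes$is_tp[outcomes$class == cl]), 0),
    fn = vapply(classes, function(cl)
      sum(truths$posture == cl & !truths$matched), 0),
    row.names = NULL)
  list(counts = counts, outcomes = outcomes)
}

#' Precision and recall from TP/FP/FN counts
#'
#' `precision = TP / (TP + FP)` and `recall = TP / (TP + FN)`. A 0/0
#' ratio is reported as `NA` (undefined), never as 0.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return Named list with `precision` and `recall`.
#' @export
precision_recall <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  list(
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_
  )
}

#' 11-point interpolated average precision
#'
#' Classic Pascal-VOC-2007 AP. From the ranked per-class outcome list
#' the precision/recall curve is traced one detection at a time, the
#' interpolated precision at recall `r` is the maximum precision over
#' all points with recall at least `r` (0 where no such point exists),
#' and AP is the mean of the interpolated precision over the 11 recall
#' grid points 0, 0.1, ..., 1.0.
#'
#' @param is_tp Logical vector of per-detection outcomes, already
#'   sorted by decreasing confidence.
#' @param n_truths Number of ground-truth boxes of the class; must be
#'   at least 1 (AP is undefined for a class with no ground truth).
#' @return AP as a fraction in `[0, 1]`.
#' @examples
#' interpolated_ap(c(TRUE, FALSE, TRUE), 2) # 28/33
#' @export
interpolated_ap <- function(is_tp, n_truths) {
  if (n_truths < 1) stop("AP undefined for n_truths < 1", call. = FALSE)
  if (length(is_tp) == 0) return(0)
  cum_tp <- cumsum(is_tp)
  precision <- cum_tp / seq_along(is_tp)
  recall <- cum_tp / n_truths
  grid <- seq(0, 1, by = 0.1)
  p_interp <- vapply(grid, function(r) {
    ok <- recall >= r - 1e-12 # guard against 0.1*k representation error
    if (any(ok)) max(precision[ok]) else 0
  }, 0)
  mean(p_interp)
}

#' Evaluate a detector against an annotation set
#'
#' Composition of [match_detections()], [precision_recall()] and
#' [interpolated_ap()]: per-class AP, precision, recall and mean IoU of
#' true-positive matches; overall (pooled-count) precision and recall;
#' mAP as the arithmetic mean of the per-class APs over all annotated
#' classes.
#'
#' @inheritParams match_detections
#' @return A list of class `fox_eval` with elements `per_class` (data
#'   frame: class, n_truth, tp, fp, fn, precision, recall, avg_iou, ap),
#'   `precision`, `recall`, `avg_iou`, `mAP`, and `n_classes`.
#' @export
evaluate_detections <- function(preds, truths, iou_threshold = 0.5) {
  m <- match_detections(preds, truths, iou_threshold)
  classes <- sort(unique(truths$posture))
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    cc <- m$counts[m$counts$class == cl, ]
    out <- m$outcomes[m$outcomes$class == cl, , drop = FALSE]
    pr <- precision_recall(cc$tp, cc$fp, cc$fn)
    data.frame(
      class = cl, n_truth = cc$tp + cc$fn, tp = cc$tp, fp = cc$fp, fn = cc$fn,
      precision = pr$precision, recall = pr$recall,
      avg_iou = if (cc$tp > 0) mean(out$iou[out$is_tp]) else NA_real_,
      ap = interpolated_ap(out$is_tp, n_truths = cc$tp + cc$fn))
  }))
  tp <- sum(per_class$tp); fp <- sum(per_class$fp); fn <- sum(per_class$fn)
  pr <- precision_recall(tp, fp, fn)
  structure(list(
    per_class = per_class,
    precision = pr$precision, recall = pr$recall,
    avg_iou = if (tp > 0) mean(m$outcomes$iou[m$outcomes$is_tp]) else NA_real_,
    mAP = mean(per_class$ap), n_classes = length(classes)
  ), class = "fox_eval")
}

#' @export
print.fox_eval <- function(x, ...) {
  cat("Detector evaluation over", x$n_classes, "classes\n")
  print(transform(x$per_class,
                  precision = round(precision, 4), recall = round(recall, 4),
                  avg_iou = round(avg_iou, 4), ap = round(ap, 4)),
        row.names = FALSE)
  cat(sprintf("overall: precision %.4f  recall %.4f  avg IoU %.4f  mAP %.4f\n",
              x$precision, x$recall, x$avg_iou, x$mAP))
  invisible(x)
}
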