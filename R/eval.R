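# Detection metrics: IoU matching, precision/recall, all-point average
# precision, and mAP aggregates.
#
# AP is the literal rank summation AP = sum_n (R_n - R_{n-1}) P_n over
# detections ordered by descending confidence (no interpolation); the
# 101-point COCO-style interpolated variant is available behind a flag for
# cross-checking. mAP is the arithmetic mean of per-category AP, excluding
# categories with no ground-truth instances.

#' Intersection over union of two axis-aligned boxes
#'
#' Boxes are 0-based half-open pixel rectangles `c(x1, y1, x2, y2)`.
#'
#' @param a,b numeric length-4 vectors.
#' @return overlap in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  if (a[3] <= a[1] || a[4] <= a[2] || b[3] <= b[1] || b[4] <= b[2])
    stop("degenerate box")
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / ((a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter)
}

# Vectorized IoU of one box against a 4-column matrix of boxes.
iou_one_many <- function(a, m) {
  iw <- pmin(a[3], m[, 3]) - pmax(a[1], m[, 1])
  ih <- pmin(a[4], m[, 4]) - pmax(a[2], m[, 2])
  inter <- pmax(iw, 0) * pmax(ih, 0)
  inter / ((a[3] - a[1]) * (a[4] - a[2]) +
             (m[, 3] - m[, 1]) * (m[, 4] - m[, 2]) - inter)
}

#' Greedy one-to-one matching of detections to ground truth
#'
#' Detections (already restricted to a single category and image, sorted by
#' descending confidence) are matched in rank order to the still-unmatched
#' ground-truth box of highest IoU, provided it reaches `iou_threshold`;
#' each ground truth is used at most once. IoU ties break toward the lower
#' ground-truth index.
#'
#' @param detections matrix/data.frame with columns x1, y1, x2, y2 (sorted
#'   by descending confidence).
#' @param ground_truth matrix/data.frame with the same columns.
#' @param iou_threshold matching threshold.
#' @return list with `tp_flags` (logical per detection), and counts `TP`,
#'   `FP`, `FN`.
#' @export
match_detections <- function(detections, ground_truth, iou_threshold = 0.5) {
  nd <- nrow(detections); ng <- nrow(ground_truth)
  flags <- logical(nd)
  if (nd > 0 && ng > 0) {
    gt <- as.matrix(ground_truth[, c("x1", "y1", "x2", "y2")])
    used <- logical(ng)
    det <- as.matrix(detections[, c("x1", "y1", "x2", "y2")])
    for (i in seq_len(nd)) {
      ious <- iou_one_many(det[i, ], gt)
      ious[used] <- -1
      j <- which.max(ious)  # ties -> lowest index
      if (ious[j] >= iou_threshold) { flags[i] <- TRUE; used[j] <- TRUE }
    }
  }
  tp <- sum(flags)
  list(tp_flags = flags, TP = tp, FP = nd - tp, FN = ng - tp)
}

#' Precision and recall from match counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`; both 0 by convention when the
#' denominator is 0.
#'
#' @param counts list with TP, FP, FN.
#' @return named numeric `c(precision, recall)`.
#' @export
precision_recall <- function(counts) {
  P <- if (counts$TP + counts$FP > 0) counts$TP / (counts$TP + counts$FP) else 0
  R <- if (counts$TP + counts$FN > 0) counts$TP / (counts$TP + counts$FN) else 0
  c(precision = P, recall = R)
}

#' Precision/recall curve over detection ranks
#'
#' Accumulates TP/FP flags in confidence-rank order: after rank n,
#' `R_n = TP_n / n_gt`, `P_n = TP_n / n`.
#'
#' @param flags logical vector, TRUE for a true positive, rank-ordered.
#' @param n_ground_truth number of ground-truth boxes of the category.
#' @return data.frame with columns `recall`, `precision`.
#' @export
pr_curve <- function(flags, n_ground_truth) {
  n <- length(flags)
  if (n == 0L)
    return(data.frame(recall = numeric(0), precision = numeric(0)))
  tp <- cumsum(flags)
  data.frame(recall = if (n_ground_truth > 0) tp / n_ground_truth else rep(0, n),
             precision = tp / seq_len(n))
}

#' All-point average precision
#'
#' The literal rank summation `AP = sum_n (R_n - R_{n-1}) P_n` with
#' `R_0 = 0`. With `interpolated = TRUE` the COCO-style 101-point
#' interpolated AP is computed instead (cross-check only, not the default).
#'
#' @param curve a [pr_curve()] result.
#' @param interpolated use 101-point interpolation.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(curve, interpolated = FALSE) {
  if (nrow(curve) == 0L) return(0)
  if (!interpolated) {
    dr <- diff(c(0, curve$recall))
    return(sum(dr * curve$precision))
  }
  rec <- curve$recall; prec <- curve$precision
  # precision envelope, then sample at 101 recall points
  for (i in rev(seq_len(length(prec) - 1))) prec[i] <- max(prec[i], prec[i + 1])
  pts <- seq(0, 1, 0.01)
  mean(vapply(pts, function(r) {
    i <- which(rec >= r)
    if (length(i) == 0L) 0 else prec[min(i)]
  }, numeric(1)))
}

#' Evaluate detections against ground truth
#'
#' @param detections data.frame with columns `image_id`, `category`
#'   (0-based), `confidence`, `x1`, `y1`, `x2`, `y2`.
#' @param ground_truth data.frame with `image_id`, `category`, `x1`, `y1`,
#'   `x2`, `y2`.
#' @param iou_thresholds IoU thresholds; default the 0.50:0.05:0.95 ladder.
#' @param conf_threshold confidence at which the scalar precision/recall
#'   operating point is reported; `NULL` picks the F1-optimal threshold at
#'   IoU 0.5 (reported in `pr_conf`).
#' @param interpolated see [average_precision()].
#' @return object of class `metric_report`: per-category AP matrix
#'   (categories x thresholds), `mAP50`, `mAP75`, `mAP50_95`, micro
#'   precision/recall, all as fractions in `[0, 1]`; `mAP_undefined` is TRUE
#'   when there is no ground truth at all.
#' @export
evaluate_detections <- function(detections, ground_truth,
                                iou_thresholds = seq(0.5, 0.95, by = 0.05),
                                conf_threshold = NULL, interpolated = FALSE) {
  if (nrow(ground_truth) == 0L) {
    return(structure(list(ap = NULL, mAP50 = NA_real_, mAP75 = NA_real_,
                          mAP50_95 = NA_real_, mAP_undefined = TRUE),
                     class = "metric_report"))
  }
  cats <- sort(unique(ground_truth$category))
  det <- detections[order(-detections$confidence, detections$image_id,
                          detections$x1, detections$y1), , drop = FALSE]
  ap <- matrix(0, nrow = length(cats), ncol = length(iou_thresholds),
               dimnames = list(as.character(cats),
                               sprintf("%.2f", iou_thresholds)))
  all_flags50 <- NULL
  for (ci in seq_along(cats)) {
    cat <- cats[ci]
    dc <- det[det$category == cat, , drop = FALSE]
    gc <- ground_truth[ground_truth$category == cat, , drop = FALSE]
    for (ti in seq_along(iou_thresholds)) {
      thr <- iou_thresholds[ti]
      # match per image, then merge flags back into global rank order
      flags <- logical(nrow(dc))
      for (img in unique(gc$image_id)) {
        di <- which(dc$image_id == img)
        gi <- gc[gc$image_id == img, , drop = FALSE]
        if (length(di) > 0)
          flags[di] <- match_detections(dc[di, , drop = FALSE], gi, thr)$tp_flags
      }
      ap[ci, ti] <- average_precision(pr_curve(flags, nrow(gc)), interpolated)
      if (abs(thr - 0.5) < 1e-9)
        all_flags50 <- rbind(all_flags50,
                             data.frame(confidence = dc$confidence, tp = flags,
                                        stringsAsFactors = FALSE))
    }
  }
  i50 <- which(abs(iou_thresholds - 0.5) < 1e-9)
  i75 <- which(abs(iou_thresholds - 0.75) < 1e-9)
  n_gt <- nrow(ground_truth)
  pr <- c(precision = NA_real_, recall = NA_real_)
  pr_conf <- NA_real_
  if (!is.null(all_flags50) && nrow(all_flags50) > 0) {
    af <- all_flags50[order(-all_flags50$confidence), , drop = FALSE]
    tp <- cumsum(af$tp)
    prec <- tp / seq_len(nrow(af)); rec <- tp / n_gt
    if (is.null(conf_threshold)) {
      f1 <- 2 * prec * rec / pmax(prec + rec, 1e-12)
      k <- which.max(f1)
    } else {
      k <- max(which(af$confidence >= conf_threshold), 1L)
    }
    pr <- c(precision = prec[k], recall = rec[k])
    pr_conf <- af$confidence[k]
  }
  structure(list(
    ap = ap, categories = cats, iou_thresholds = iou_thresholds,
    mAP50 = if (length(i50)) mean(ap[, i50]) else NA_real_,
    mAP75 = if (length(i75)) mean(ap[, i75]) else NA_real_,
    mAP50_95 = mean(colMeans(ap)),
    precision = unname(pr["precision"]), recall = unname(pr["recall"]),
    pr_conf = pr_conf, mAP_undefined = FALSE), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  if (isTRUE(x$mAP_undefined)) {
    cat("metric report: no ground truth; mAP undefined\n")
    return(invisible(x))
  }
  cat(sprintf("mAP50 %.2f%%  mAP75 %.2f%%  mAP50:95 %.2f%%\n",
              100 * x$mAP50, 100 * x$mAP75, 100 * x$mAP50_95))
  if (!is.na(x$precision))
    cat(sprintf("P %.2f%%  R %.2f%% (at confidence %.3f)\n",
                100 * x$precision, 100 * x$recall, x$pr_conf))
  invisible(x)
}
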