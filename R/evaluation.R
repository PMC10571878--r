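# ---------------------------------------------------------------------------
# Detection evaluation: greedy IoU matching, precision / recall, per-class
# average precision by all-points PR-curve integration, mAP@0.5, and a
# confusion matrix with an explicit background row/column. Counting is per
# detection / per ground-truth object (the standard detection-metric
# reading), at IoU threshold 0.5.
# ---------------------------------------------------------------------------

empty_dets <- function() {
  data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0), y2 = numeric(0),
             conf = numeric(0), class_id = integer(0))
}

as_gt_matrix <- function(gts) {
  if (is.data.frame(gts)) gts <- as.matrix(gts[, c("x1", "y1", "x2", "y2", "class_id")])
  if (is.null(dim(gts))) gts <- matrix(gts, nrow = 1)
  gts
}

#' Greedy one-to-one matching of detections to ground truth
#'
#' Detections are processed in decreasing confidence order; each is matched
#' to the unconsumed same-class ground-truth box of highest IoU at or above
#' the threshold. Ties in confidence break by input order.
#'
#' @param dets data frame with x1, y1, x2, y2, conf, class_id.
#' @param gts matrix/data frame with columns x1, y1, x2, y2, class_id.
#' @param iou_thresh match threshold (default 0.5).
#' @return list: `tp` logical per detection (input order), `gt_matched`
#'   logical per ground truth, `order` (confidence ranking), and TP/FP/FN
#'   counts.
#' @export
match_detections <- function(dets, gts, iou_thresh = 0.5) {
  gts <- as_gt_matrix(gts)
  nd <- nrow(dets); ng <- nrow(gts)
  tp <- logical(nd)
  gmatch <- integer(nd)
  used <- logical(ng)
  ord <- if (nd) order(-dets$conf, seq_len(nd)) else integer(0)
  if (nd && ng) {
    ious <- box_iou(as.matrix(dets[, c("x1", "y1", "x2", "y2")]),
                    gts[, 1:4, drop = FALSE])
    for (i in ord) {
      cand <- which(!used & gts[, 5] == dets$class_id[i] & ious[i, ] >= iou_thresh)
      if (length(cand)) {
        best <- cand[which.max(ious[i, cand])]
        used[best] <- TRUE
        tp[i] <- TRUE
        gmatch[i] <- best
      }
    }
  }
  list(tp = tp, gt_matched = used, order = ord,
       n_tp = sum(tp), n_fp = nd - sum(tp), n_fn = ng - sum(used))
}

#' Precision and recall from a match result
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`; both defined as 0 when their
#' denominator is empty.
#'
#' @param m a [match_detections()] result (or any list with `n_tp`, `n_fp`,
#'   `n_fn`).
#' @return named numeric `c(precision, recall)`.
#' @export
precision_recall <- function(m) {
  p <- if (m$n_tp + m$n_fp > 0) m$n_tp / (m$n_tp + m$n_fp) else 0
  r <- if (m$n_tp + m$n_fn > 0) m$n_tp / (m$n_tp + m$n_fn) else 0
  c(precision = p, recall = r)
}

#' Average precision from ranked true/false-positive flags
#'
#' All-points interpolation: the precision envelope is made monotone
#' non-increasing and the area under the precision-recall curve summed over
#' every recall step.
#'
#' @param tp_ranked logical vector of per-detection TP flags, sorted by
#'   decreasing confidence.
#' @param n_gt number of ground-truth boxes of the class (>= 1).
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(tp_ranked, n_gt) {
  stopifnot(n_gt >= 1)
  if (!length(tp_ranked)) return(0)
  ctp <- cumsum(tp_ranked)
  cfp <- cumsum(!tp_ranked)
  rec <- ctp / n_gt
  prec <- ctp / (ctp + cfp)
  mrec <- c(0, rec, 1)
  mpre <- c(0, prec, 0)
  for (i in seq(length(mpre) - 1, 1)) mpre[i] <- max(mpre[i], mpre[i + 1])
  idx <- which(mrec[-1] != mrec[-length(mrec)])
  sum((mrec[idx + 1] - mrec[idx]) * mpre[idx + 1])
}

#' Mean average precision
#' @param aps numeric vector of per-class APs (classes with ground truth).
#' @return their arithmetic mean.
#' @export
mean_ap <- function(aps) {
  aps <- aps[!is.na(aps)]
  stopifnot(length(aps) >= 1)
  mean(aps)
}

#' Background-aware confusion matrix
#'
#' Rows are true classes plus a final background row; columns are predicted
#' classes plus a final background column. Detections at or above
#' `conf_thresh` are greedily matched to ground truth by IoU regardless of
#' class: matched pairs land at (true, predicted); unmatched ground truth in
#' the background column (missed detections); unmatched detections in the
#' background row (false detections of the background).
#'
#' @param dets_list,gts_list per-image detections / ground truth.
#' @param num_classes number of object classes N; the matrix is (N+1)^2.
#' @param conf_thresh detection confidence threshold.
#' @param iou_thresh match threshold.
#' @param normalize row-normalize (rows with mass sum to 1).
#' @return (N+1) x (N+1) matrix, dimnames class labels plus "background".
#' @export
confusion_matrix <- function(dets_list, gts_list, num_classes,
                             conf_thresh = 0.5, iou_thresh = 0.5,
                             normalize = FALSE) {
  N <- num_classes
  cm <- matrix(0, N + 1, N + 1)
  labs <- c(paste0("class", 0:(N - 1)), "background")
  dimnames(cm) <- list(true = labs, predicted = labs)
  for (i in seq_along(gts_list)) {
    gts <- as_gt_matrix(gts_list[[i]])
    dets <- if (i <= length(dets_list) && !is.null(dets_list[[i]])) dets_list[[i]] else empty_dets()
    dets <- dets[dets$conf >= conf_thresh, , drop = FALSE]
    nd <- nrow(dets); ng <- nrow(gts)
    used <- logical(ng)
    dmatched <- logical(nd)
    if (nd && ng) {
      ious <- box_iou(as.matrix(dets[, c("x1", "y1", "x2", "y2")]),
                      gts[, 1:4, drop = FALSE])
      for (k in order(-dets$conf, seq_len(nd))) {
        cand <- which(!used & ious[k, ] >= iou_thresh)
        if (length(cand)) {
          best <- cand[which.max(ious[k, cand])]
          used[best] <- TRUE
          dmatched[k] <- TRUE
          cm[gts[best, 5] + 1, dets$class_id[k] + 1] <-
            cm[gts[best, 5] + 1, dets$class_id[k] + 1] + 1
        }
      }
    }
    if (ng) for (b in which(!used)) cm[gts[b, 5] + 1, N + 1] <- cm[gts[b, 5] + 1, N + 1] + 1
    if (nd) for (k in which(!dmatched)) cm[N + 1, dets$class_id[k] + 1] <-
        cm[N + 1, dets$class_id[k] + 1] + 1
  }
  if (normalize) {
    rs <- rowSums(cm)
    nz <- rs > 0
    cm[nz, ] <- cm[nz, , drop = FALSE] / rs[nz]
  }
  cm
}

#' Evaluate detections against ground truth
#'
#' Computes per-class AP over the dataset-wide confidence ranking, mAP@0.5,
#' macro-averaged precision/recall at the evaluation confidence threshold,
#' and the background-aware confusion matrix.
#'
#' @param dets_list list (per image) of detection data frames.
#' @param gts_list list (per image) of ground-truth corner matrices
#'   (x1, y1, x2, y2, class_id).
#' @param num_classes number of classes.
#' @param iou_thresh IoU threshold (0.5 for mAP@0.5).
#' @param conf_thresh confidence threshold for P/R and the confusion matrix.
#' @return an `eval_report` list: `per_class` data frame (class, n_gt, ap,
#'   precision, recall), `map`, `precision`, `recall`, `confusion`,
#'   `confusion_normalized`.
#' @export
evaluate_detections <- function(dets_list, gts_list, num_classes,
                                iou_thresh = 0.5, conf_thresh = 0.5) {
  N <- num_classes
  # dataset-wide ranking per class for AP
  recs <- list()
  for (i in seq_along(gts_list)) {
    dets <- if (i <= length(dets_list) && !is.null(dets_list[[i]])) dets_list[[i]] else empty_dets()
    m <- match_detections(dets, gts_list[[i]], iou_thresh)
    if (nrow(dets)) {
      recs[[length(recs) + 1]] <- data.frame(conf = dets$conf,
                                             class_id = dets$class_id,
                                             tp = m$tp, img = i)
    }
  }
  allrec <- if (length(recs)) do.call(rbind, recs) else
    data.frame(conf = numeric(0), class_id = integer(0), tp = logical(0), img = integer(0))
  gt_all <- do.call(rbind, lapply(gts_list, as_gt_matrix))
  n_gt_class <- vapply(0:(N - 1), function(cl) sum(gt_all[, 5] == cl), numeric(1))

  per_class <- data.frame(class = 0:(N - 1), n_gt = n_gt_class, ap = NA_real_,
                          precision = NA_real_, recall = NA_real_)
  for (cl in 0:(N - 1)) {
    if (n_gt_class[cl + 1] == 0) next
    sub <- allrec[allrec$class_id == cl, , drop = FALSE]
    sub <- sub[order(-sub$conf, sub$img), , drop = FALSE]
    per_class$ap[cl + 1] <- average_precision(sub$tp, n_gt_class[cl + 1])
    hi <- sub[sub$conf >= conf_thresh, , drop = FALSE]
    ntp <- sum(hi$tp); nfp <- nrow(hi) - ntp
    per_class$precision[cl + 1] <- if (ntp + nfp > 0) ntp / (ntp + nfp) else 0
    per_class$recall[cl + 1] <- ntp / n_gt_class[cl + 1]
  }
  defined <- !is.na(per_class$ap)
  rep <- list(per_class = per_class,
              map = mean_ap(per_class$ap[defined]),
              precision = mean(per_class$precision[defined]),
              recall = mean(per_class$recall[defined]),
              confusion = confusion_matrix(dets_list, gts_list, N,
                                           conf_thresh, iou_thresh, FALSE),
              confusion_normalized = confusion_matrix(dets_list, gts_list, N,
                                                      conf_thresh, iou_thresh, TRUE))
  class(rep) <- "eval_report"
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("mAP@0.5 %.4f | precision %.4f | recall %.4f (conf >= 0.5)\n",
              x$map, x$precision, x$recall))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}
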