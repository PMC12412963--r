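# ---------------------------------------------------------------------------
# Detection accuracy (precision, recall, AP/mAP at IoU 0.5) and object-count
# regression metrics (MAE, RMSE, R^2).
# ---------------------------------------------------------------------------

#' Match detections to ground truths
#'
#' Score-descending greedy one-to-one matching per class at a fixed IoU
#' threshold. Unmatched detections are false positives, unmatched truths
#' false negatives.
#'
#' @param detections Data frame `cx, cy, w, h, class, score` (one image).
#' @param truths Data frame `cx, cy, w, h, class` (same units).
#' @param iou_thr Match threshold (0.5).
#' @return The detections with a logical `tp` column (score-descending),
#'   plus attributes `n_truth` (per-class truth counts) and `fn` (count).
#' @export
match_detections <- function(detections, truths, iou_thr = 0.5) {
  n <- nrow(detections)
  ord <- if (n > 0) order(-detections$score) else integer()
  d <- detections[ord, , drop = FALSE]
  tp <- logical(n)
  used <- rep(FALSE, nrow(truths))
  if (n > 0 && nrow(truths) > 0) {
    iou <- box_iou_xywh(as.matrix(d[, c("cx", "cy", "w", "h")]),
                        as.matrix(truths[, c("cx", "cy", "w", "h")]))
    for (i in seq_len(n)) {
      cand <- which(!used & truths$class == d$class[i] & iou[i, ] >= iou_thr)
      if (length(cand) > 0) {
        j <- cand[which.max(iou[i, cand])]
        used[j] <- TRUE
        tp[i] <- TRUE
      }
    }
  }
  d$tp <- tp
  attr(d, "n_truth") <- table(factor(truths$class, levels = sort(unique(truths$class))))
  attr(d, "fn") <- sum(!used)
  d
}

#' Average precision from a ranked TP/FP sequence
#'
#' Integrates the precision–recall curve by 101-point interpolation
#' (precision at each recall knot taken as the maximum precision at any
#' recall at least that large).
#'
#' @param tp Logical vector in decreasing-score order.
#' @param n_truths Number of ground-truth objects of the class.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(tp, n_truths) {
  if (n_truths == 0) return(NA_real_)
  if (length(tp) == 0) return(0)
  ctp <- cumsum(tp); cfp <- cumsum(!tp)
  recall <- ctp / n_truths
  precision <- ctp / (ctp + cfp)
  knots <- seq(0, 1, length.out = 101L)
  mean(vapply(knots, function(r) {
    i <- which(recall >= r)
    if (length(i) == 0) 0 else max(precision[min(i):length(precision)])
  }, 0))
}

#' Detection metrics over a set of images
#'
#' Pools matches across images and reports per-class precision, recall and
#' AP at IoU 0.5, plus their class means. Classes with zero ground truths
#' are excluded from the mAP mean.
#'
#' @param det_list List of per-image detection data frames.
#' @param truth_list List of per-image truth data frames (same order).
#' @param num_classes Total number of classes.
#' @param iou_thr Match threshold.
#' @return A `ycf_metrics` list with a per-class table and `mAP`.
#' @export
evaluate_detections <- function(det_list, truth_list, num_classes,
                                iou_thr = 0.5) {
  stopifnot(length(det_list) == length(truth_list))
  rows <- list()
  for (i in seq_along(det_list)) {
    m <- match_detections(det_list[[i]], truth_list[[i]], iou_thr)
    if (nrow(m) > 0) rows[[length(rows) + 1L]] <- m[, c("class", "score", "tp")]
  }
  all_d <- if (length(rows)) do.call(rbind, rows)
           else data.frame(class = integer(), score = numeric(), tp = logical())
  truth_n <- integer(num_classes)
  for (tr in truth_list)
    for (k in tr$class) truth_n[k + 1L] <- truth_n[k + 1L] + 1L
  per_class <- data.frame(class = 0:(num_classes - 1L), n_truth = truth_n,
                          tp = 0L, fp = 0L, precision = 0, recall = 0, ap = NA_real_)
  for (k in seq_len(num_classes)) {
    dk <- all_d[all_d$class == k - 1L, , drop = FALSE]
    dk <- dk[order(-dk$score), , drop = FALSE]
    ntp <- sum(dk$tp); nfp <- sum(!dk$tp)
    per_class$tp[k] <- ntp; per_class$fp[k] <- nfp
    per_class$precision[k] <- if (ntp + nfp > 0) ntp / (ntp + nfp) else 0
    per_class$recall[k] <- if (truth_n[k] > 0) ntp / truth_n[k] else 0
    per_class$ap[k] <- average_precision(dk$tp, truth_n[k])
  }
  seen <- per_class$n_truth > 0
  structure(list(per_class = per_class,
                 precision = mean(per_class$precision[seen]),
                 recall = mean(per_class$recall[seen]),
                 mAP = mean(per_class$ap[seen]),
                 iou_thr = iou_thr), class = "ycf_metrics")
}

#' @export
print.ycf_metrics <- function(x, ...) {
  print(x$per_class, row.names = FALSE)
  cat(sprintf("P %.3f | R %.3f | mAP@%.2f %.3f\n",
              x$precision, x$recall, x$iou_thr, x$mAP))
  invisible(x)
}

#' Object-count agreement metrics
#'
#' Per-image predicted vs. true object counts summarized by mean absolute
#' error, root-mean-square error, and the coefficient of determination
#' `R^2 = 1 - SS_res/SS_tot` (which may be negative).
#'
#' @param true_counts,predicted_counts Equal-length non-negative vectors,
#'   `n >= 2`; `true_counts` must not be constant (R^2 undefined).
#' @return A `ycf_counts` list: per-image table, `mae`, `rmse`, `r2`.
#' @export
count_analysis <- function(true_counts, predicted_counts) {
  if (length(true_counts) != length(predicted_counts)) stop("length mismatch")
  if (length(true_counts) < 2L) stop("need at least two images")
  if (stats::var(true_counts) == 0)
    stop("R^2 is undefined for constant true counts")
  res <- true_counts - predicted_counts
  structure(list(
    per_image = data.frame(true = true_counts, predicted = predicted_counts),
    mae = mean(abs(res)),
    rmse = sqrt(mean(res^2)),
    r2 = 1 - sum(res^2) / sum((true_counts - mean(true_counts))^2)),
    class = "ycf_counts")
}

#' @export
print.ycf_counts <- function(x, ...) {
  cat(sprintf("count analysis over %d images: MAE %.3f | RMSE %.3f | R2 %.3f\n",
              nrow(x$per_image), x$mae, x$rmse, x$r2))
  invisible(x)
}

#' Per-image object counts from detections
#'
#' @param det_list List of per-image detection data frames (post-NMS).
#' @param conf Confidence floor.
#' @param per_class Count per class instead of pooling all classes.
#' @return Integer vector (pooled) or matrix (per class x image).
#' @export
detection_counts <- function(det_list, conf = 0.25, per_class = FALSE) {
  if (!per_class)
    return(vapply(det_list, function(d) sum(d$score >= conf), 0L))
  classes <- sort(unique(unlist(lapply(det_list, function(d) d$class))))
  vapply(det_list, function(d)
    vapply(classes, function(k) sum(d$class == k & d$score >= conf), 0L),
    integer(length(classes)))
}

#' Export the per-class metric table
#' @param metrics A [evaluate_detections()] result.
#' @param path CSV path.
#' @export
write_metrics <- function(metrics, path) {
  utils::write.csv(metrics$per_class, path, row.names = FALSE)
  invisible(path)
}
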