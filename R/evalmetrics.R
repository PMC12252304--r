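# ---------------------------------------------------------------------------
# Detection evaluation: greedy IoU matching, precision/recall, the
# precision-recall sweep, AP (all-point envelope integration) and mAP.
# ---------------------------------------------------------------------------

#' Pairwise IoU between two sets of boxes
#'
#' @param a,b data.frames with cx/cy/w/h in any common coordinate system.
#' @return `nrow(a)` x `nrow(b)` IoU matrix.
#' @export
box_iou <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(matrix(0, nrow(a), nrow(b)))
  ax0 <- a$cx - a$w / 2; ax1 <- a$cx + a$w / 2
  ay0 <- a$cy - a$h / 2; ay1 <- a$cy + a$h / 2
  bx0 <- b$cx - b$w / 2; bx1 <- b$cx + b$w / 2
  by0 <- b$cy - b$h / 2; by1 <- b$cy + b$h / 2
  iw <- pmax(0, outer(ax1, bx1, pmin) - outer(ax0, bx0, pmax))
  ih <- pmax(0, outer(ay1, by1, pmin) - outer(ay0, by0, pmax))
  inter <- iw * ih
  union <- outer(a$w * a$h, b$w * b$h, "+") - inter
  ifelse(union > 0, inter / union, 0)
}

#' Greedy TP/FP assignment of detections against ground truth
#'
#' Detections are processed in descending confidence; each is a true positive
#' iff it overlaps an as-yet unmatched same-class truth box at IoU >= the
#' threshold (taking the highest-IoU such truth). Every truth box is matched
#' at most once; unmatched truths are false negatives.
#'
#' @param detections data.frame class/cx/cy/w/h/conf.
#' @param ground_truth data.frame class/cx/cy/w/h.
#' @param iou_threshold matching threshold (default 0.5).
#' @return list: `tp` logical per detection (in confidence order), `order`
#'   the ordering applied, `fn` count of unmatched truths, `counts` a
#'   TP/FP/FN/TN list (TN fixed at 0: undefined for detection).
#' @export
match_detections <- function(detections, ground_truth, iou_threshold = 0.5) {
  o <- order(-detections$conf)
  det <- detections[o, , drop = FALSE]
  nd <- nrow(det); ng <- nrow(ground_truth)
  tp <- logical(nd)
  matched <- logical(ng)
  if (nd && ng) {
    iou <- box_iou(det, ground_truth)
    for (i in seq_len(nd)) {
      cand <- which(!matched & ground_truth$class == det$class[i] &
                      iou[i, ] >= iou_threshold)
      if (length(cand)) {
        j <- cand[which.max(iou[i, cand])]
        matched[j] <- TRUE
        tp[i] <- TRUE
      }
    }
  }
  counts <- list(TP = sum(tp), FP = sum(!tp), FN = sum(!matched), TN = 0L)
  list(tp = tp, order = o, fn = sum(!matched), counts = counts)
}

#' Precision = TP / (TP + FP)
#'
#' Returns 0 when no positives were predicted (guarded division).
#' @param counts list with TP and FP (e.g. from [match_detections()]).
#' @export
precision <- function(counts) {
  d <- counts$TP + counts$FP
  if (d == 0) 0 else counts$TP / d
}

#' Recall = TP / (TP + FN)
#'
#' Returns 0 when there are no positive samples (guarded division).
#' @param counts list with TP and FN.
#' @export
recall <- function(counts) {
  d <- counts$TP + counts$FN
  if (d == 0) 0 else counts$TP / d
}

#' Precision-recall curve for one class over a set of images
#'
#' Pools detections of one class across images, sweeps the confidence
#' ranking, and returns cumulative precision/recall. Matching is greedy
#' per image as in [match_detections()].
#'
#' @param detections list (one per image) of data.frames
#'   class/cx/cy/w/h/conf.
#' @param ground_truth list (one per image) of data.frames class/cx/cy/w/h.
#' @param class class index to evaluate.
#' @param iou_threshold matching threshold.
#' @return object of class `pr_curve`: list with `precision`, `recall`,
#'   `conf` (parallel vectors in rank order), `n_truth`, `class`.
#' @export
pr_curve <- function(detections, ground_truth, class, iou_threshold = 0.5) {
  stopifnot(length(detections) == length(ground_truth))
  recs <- list()
  n_truth <- 0L
  for (i in seq_along(detections)) {
    gt <- ground_truth[[i]]
    gt <- gt[gt$class == class, , drop = FALSE]
    dt <- detections[[i]]
    dt <- dt[dt$class == class, , drop = FALSE]
    n_truth <- n_truth + nrow(gt)
    if (!nrow(dt)) next
    m <- match_detections(dt, gt, iou_threshold)
    recs[[length(recs) + 1L]] <-
      data.frame(conf = dt$conf[m$order], tp = m$tp)
  }
  all <- if (length(recs)) do.call(rbind, recs) else
    data.frame(conf = numeric(0), tp = logical(0))
  all <- all[order(-all$conf), , drop = FALSE]
  ctp <- cumsum(all$tp); cfp <- cumsum(!all$tp)
  prec <- if (nrow(all)) ctp / (ctp + cfp) else numeric(0)
  rec <- if (n_truth > 0) ctp / n_truth else rep(NaN, nrow(all))
  structure(list(precision = prec, recall = rec, conf = all$conf,
                 n_truth = n_truth, class = class),
            class = "pr_curve")
}

#' Average precision: area under the precision envelope vs recall
#'
#' All-point interpolation: precision is replaced by its running maximum from
#' the right (the envelope) and integrated over recall. A 101-point
#' interpolated variant is available.
#'
#' @param curve a [pr_curve()].
#' @param interpolation `"all"` (default) or `"101"`.
#' @return AP in [0,1]; `NA` (with a warning) when the class has no truth
#'   instances, in which case it must be excluded from mAP.
#' @export
average_precision <- function(curve, interpolation = c("all", "101")) {
  interpolation <- match.arg(interpolation)
  if (curve$n_truth == 0) {
    warning("AP undefined for class ", curve$class, ": no ground-truth instances")
    return(NA_real_)
  }
  if (!length(curve$recall)) return(0)
  r <- c(0, curve$recall)
  p <- c(1, curve$precision)
  env <- rev(cummax(rev(p)))
  if (interpolation == "all") {
    sum(diff(r) * env[-1])
  } else {
    grid <- seq(0, 1, length.out = 101)
    pi <- vapply(grid, function(g) {
      ok <- r >= g
      if (any(ok)) max(env[ok]) else 0
    }, numeric(1))
    mean(pi)
  }
}

#' Mean average precision over classes
#'
#' @param aps numeric vector of per-class APs; `NA` entries (classes without
#'   truth instances) are excluded with a warning.
#' @return mAP in [0,1].
#' @export
mean_ap <- function(aps) {
  if (any(is.na(aps))) {
    warning(sum(is.na(aps)), " class(es) without truth instances excluded from mAP")
    aps <- aps[!is.na(aps)]
  }
  if (!length(aps)) return(NA_real_)
  mean(aps)
}

#' Frames per second from per-frame inference time
#'
#' A hardware-dependent convenience: FPS = 1 / inference_time_per_frame.
#' Reported for information only; never comparable across machines.
#' @param inference_time_per_frame seconds per frame.
#' @export
fps <- function(inference_time_per_frame) {
  stopifnot(inference_time_per_frame > 0)
  1 / inference_time_per_frame
}

#' Evaluate detections over a dataset
#'
#' Computes per-class AP, mAP, and single precision/recall values taken at
#' the confidence threshold that maximizes F1 (per the headline class).
#'
#' @param detections,ground_truth per-image lists as in [pr_curve()].
#' @param classes class indices present in the task (default 0:1).
#' @param iou_threshold matching threshold for AP (default 0.5: "mAP@0.5").
#' @param headline_class class whose AP/P/R are reported as the headline
#'   (default 1, the inner/stomatal class).
#' @return list with `ap` (named per class), `map`, `map_headline`,
#'   `precision`, `recall`, `f1_conf`.
#' @export
evaluate_detections <- function(detections, ground_truth, classes = c(0L, 1L),
                                iou_threshold = 0.5, headline_class = 1L) {
  curves <- lapply(classes, function(cl)
    pr_curve(detections, ground_truth, cl, iou_threshold))
  names(curves) <- as.character(classes)
  aps <- vapply(curves, function(cu)
    suppressWarnings(average_precision(cu)), numeric(1))
  hc <- curves[[as.character(headline_class)]]
  best <- list(p = 0, r = 0, conf = NA_real_)
  if (length(hc$recall)) {
    f1 <- 2 * hc$precision * hc$recall /
      pmax(hc$precision + hc$recall, 1e-12)
    i <- which.max(f1)
    best <- list(p = hc$precision[i], r = hc$recall[i], conf = hc$conf[i])
  }
  list(ap = aps, map = suppressWarnings(mean_ap(aps)),
       map_headline = aps[[as.character(headline_class)]],
       precision = best$p, recall = best$r, f1_conf = best$conf)
}
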