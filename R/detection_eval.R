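## Object-detection evaluation: IoU matching, precision-recall / average
## precision at a fixed IoU threshold, and per-image count MAE/RMSE.

#' Intersection over union of two boxes
#'
#' Boxes are numeric `c(x_min, y_min, x_max, y_max)` (half-open, so area
#' is `(x_max - x_min) * (y_max - y_min)`); disjoint boxes score 0.
#'
#' @param a,b boxes.
#' @return IoU in `[0, 1]`.
#' @examples
#' iou(c(0, 0, 1, 1), c(0.5, 0, 1.5, 1))  # 1/3
#' @export
iou <- function(a, b) {
  if (a[3] <= a[1] || a[4] <= a[2] || b[3] <= b[1] || b[4] <= b[2]) {
    stopf("degenerate box")
  }
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  inter / ((a[3] - a[1]) * (a[4] - a[2]) +
             (b[3] - b[1]) * (b[4] - b[2]) - inter)
}

## IoU matrix between two detection tables (rows of dets x rows of gts)
iou_matrix <- function(dets, gts) {
  n <- nrow(dets); m <- nrow(gts)
  area_d <- (dets$x_max - dets$x_min) * (dets$y_max - dets$y_min)
  area_g <- (gts$x_max - gts$x_min) * (gts$y_max - gts$y_min)
  out <- matrix(0, n, m)
  for (j in seq_len(m)) {
    iw <- pmax(0, pmin(dets$x_max, gts$x_max[j]) -
                 pmax(dets$x_min, gts$x_min[j]))
    ih <- pmax(0, pmin(dets$y_max, gts$y_max[j]) -
                 pmax(dets$y_min, gts$y_min[j]))
    inter <- iw * ih
    out[, j] <- inter / (area_d + area_g[j] - inter)
  }
  out
}

#' Match detections to ground truth
#'
#' Greedy confidence-ordered matching, the standard protocol for
#' single-class detector evaluation: detections are visited by descending
#' confidence; each is matched to the not-yet-matched ground-truth box of
#' highest IoU above the threshold (ties toward the lower ground-truth
#' index), else labelled a false positive.  Ground-truth boxes matched by
#' nobody are false negatives.  Matching is per image (`image_id` frames
#' are matched independently).
#'
#' @param dets detections with confidences.
#' @param gts ground-truth boxes (same pixel frame per image).
#' @param iou_thresh matching threshold (default 0.5).
#' @return a `match_result` list: `detections` (the input sorted by
#'   descending confidence with `is_tp`, `matched_gt`, `iou` columns),
#'   `n_gt`, `n_fn`.
#' @export
match_detections <- function(dets, gts, iou_thresh = 0.5) {
  ord <- order(-dets$confidence)
  dets <- dets[ord, , drop = FALSE]
  dets$is_tp <- FALSE
  dets$matched_gt <- NA_integer_
  dets$iou <- NA_real_
  gts$.gt_id <- seq_len(nrow(gts))
  for (img in unique(dets$image_id)) {
    di <- which(dets$image_id == img)
    gi <- which(gts$image_id == img)
    if (!length(gi)) next
    M <- iou_matrix(dets[di, , drop = FALSE], gts[gi, , drop = FALSE])
    taken <- rep(FALSE, length(gi))
    for (r in seq_along(di)) {
      cand <- which(!taken & M[r, ] >= iou_thresh)
      if (!length(cand)) next
      best <- cand[order(-M[r, cand], cand)][1]
      taken[best] <- TRUE
      dets$is_tp[di[r]] <- TRUE
      dets$matched_gt[di[r]] <- gts$.gt_id[gi[best]]
      dets$iou[di[r]] <- M[r, best]
    }
  }
  structure(list(detections = dets, n_gt = nrow(gts),
                 n_fn = nrow(gts) - sum(dets$is_tp)),
            class = "match_result")
}

#' Average precision and the precision-recall curve
#'
#' Sweeps the precision-recall points over descending confidence and
#' integrates the area under the precision envelope (all-point
#' interpolation, as used for COCO-style single-threshold AP).  With a
#' single class, mAP equals AP.
#'
#' @param match a [match_detections()] result (requires at least one
#'   ground-truth box).
#' @return `list(ap, pr)` where `pr` is a
#'   `data.frame(recall, precision, confidence)`.
#' @export
average_precision <- function(match) {
  if (match$n_gt < 1) stopf("AP is undefined without ground truth")
  d <- match$detections
  if (!nrow(d)) {
    return(list(ap = 0, pr = data.frame(recall = numeric(),
                                        precision = numeric(),
                                        confidence = numeric())))
  }
  tp <- cumsum(d$is_tp)
  fp <- cumsum(!d$is_tp)
  recall <- tp / match$n_gt
  precision <- tp / (tp + fp)
  env <- rev(cummax(rev(precision)))
  ap <- sum(diff(c(0, recall)) * env)
  list(ap = ap, pr = data.frame(recall = recall, precision = precision,
                                confidence = d$confidence))
}

#' Count MAE and RMSE
#'
#' Mean absolute and root-mean-square error of paired per-image head
#' counts.
#'
#' @param pred_counts,true_counts equal-length numeric vectors.
#' @return named numeric `c(mae, rmse)`; always `rmse >= mae`.
#' @examples
#' count_errors(c(3, 5), c(4, 5))  # mae 0.5, rmse ~0.7071
#' @export
count_errors <- function(pred_counts, true_counts) {
  if (length(pred_counts) != length(true_counts)) {
    stopf("count vectors differ in length")
  }
  d <- pred_counts - true_counts
  c(mae = mean(abs(d)), rmse = sqrt(mean(d^2)))
}

#' Evaluate a detector against ground truth
#'
#' Convenience wrapper: matching, AP and per-image count errors in one
#' call.
#'
#' @param dets predicted detections.
#' @param gts ground-truth boxes.
#' @param iou_thresh matching IoU threshold (default 0.5).
#' @return list with `ap`, `pr`, `mae`, `rmse`, `per_image`
#'   (`data.frame(image_id, pred, truth)`) and the `match_result`.
#' @export
evaluate_detections <- function(dets, gts, iou_thresh = 0.5) {
  match <- match_detections(dets, gts, iou_thresh)
  ap <- average_precision(match)
  ids <- sort(unique(c(dets$image_id, gts$image_id)))
  per_image <- data.frame(
    image_id = ids,
    pred = as.integer(table(factor(dets$image_id, levels = ids))),
    truth = as.integer(table(factor(gts$image_id, levels = ids))))
  err <- count_errors(per_image$pred, per_image$truth)
  list(ap = ap$ap, pr = ap$pr, mae = unname(err["mae"]),
       rmse = unname(err["rmse"]), per_image = per_image, match = match,
       interpolation = "all_point")
}
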