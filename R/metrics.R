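# Evaluation protocol: windowed confusion counts between edge maps,
# precision / recall / Dice / Jaccard, area relative error, and mask
# average precision.

#' Windowed confusion counts between two edge maps
#'
#' Two N x N windows slide simultaneously (stride 1, pad-with-false) over
#' the predicted and the ground-truth edge map. At each pixel position a
#' map "detects" an edge if its window contains at least one edge pixel;
#' the four joint outcomes are tallied. With `window = 1` this reduces to
#' the plain pixelwise confusion matrix.
#'
#' @param pred,truth Logical matrices of identical shape.
#' @param window Odd window side length >= 1; default 3.
#' @return Object of class `"confusion_counts"`: list with integer `TP`,
#'   `FP`, `FN`, `TN` summing to the number of pixel positions.
#' @export
windowed_confusion <- function(pred, truth, window = 3L) {
  assert_mask(pred, "pred"); assert_mask(truth, "truth")
  if (!all(dim(pred) == dim(truth)))
    stop("pred and truth shapes differ", call. = FALSE)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be odd and >= 1", call. = FALSE)
  se <- se_square(window)
  dp <- dilate_mask(pred, se)   # window contains >= 1 edge pixel
  dt <- dilate_mask(truth, se)
  structure(list(TP = sum(dp & dt), FP = sum(dp & !dt),
                 FN = sum(!dp & dt), TN = sum(!dp & !dt)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP=%d FP=%d FN=%d TN=%d\n", x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

rate_or_na <- function(num, den, what) {
  if (den <= 0) {
    warning(what, " undefined (zero denominator); returning NA")
    return(NA_real_)
  }
  num / den
}

#' Precision, recall, Dice and Jaccard from confusion counts
#'
#' The four standard formulas: precision = TP/(TP+FP),
#' recall = TP/(TP+FN), Dice = 2TP/(2TP+FP+FN),
#' Jaccard = TP/(TP+FP+FN). A zero denominator yields `NA` with a warning.
#'
#' @param counts A [windowed_confusion()] result (or any list with `TP`,
#'   `FP`, `FN`).
#' @return A number in \[0, 1\], or `NA`.
#' @export
precision_score <- function(counts) rate_or_na(counts$TP, counts$TP + counts$FP, "precision")

#' @rdname precision_score
#' @export
recall_score <- function(counts) rate_or_na(counts$TP, counts$TP + counts$FN, "recall")

#' @rdname precision_score
#' @export
dice_score <- function(counts)
  rate_or_na(2 * counts$TP, 2 * counts$TP + counts$FP + counts$FN, "Dice")

#' @rdname precision_score
#' @export
jaccard_score <- function(counts)
  rate_or_na(counts$TP, counts$TP + counts$FP + counts$FN, "Jaccard")

#' Dice and Jaccard from precision/recall rates
#'
#' Algebraic identities that follow from the count-based formulas:
#' D = 2PR/(P+R) and J = PR/(P+R-PR). Useful for reconstructing overlap
#' scores from published precision/recall pairs.
#'
#' @param p,r Precision and recall, in \[0, 1\] (or both on a percent
#'   scale, in which case the result is on the same scale).
#' @return Dice (respectively Jaccard) on the scale of the inputs.
#' @export
dice_from_rates <- function(p, r) 2 * p * r / (p + r)

#' @rdname dice_from_rates
#' @export
jaccard_from_rates <- function(p, r) {
  scale <- if (max(p, r) > 1) 100 else 1
  p <- p / scale; r <- r / scale
  scale * p * r / (p + r - p * r)
}

#' Signed area relative error of a detected contour
#'
#' rs = (S1 - S2) / S1 where S1 is the ground-truth foreground pixel count
#' and S2 the number of pixels enclosed by the predicted contour (the edge
#' map with its interior filled via [fill_holes()]). Negative values mean
#' over-segmentation.
#'
#' @param true_mask Logical matrix; ground-truth foreground.
#' @param pred_edges Logical matrix; predicted edge map (same shape).
#' @return Signed real number.
#' @export
area_relative_error <- function(true_mask, pred_edges) {
  assert_mask(true_mask, "true_mask"); assert_mask(pred_edges, "pred_edges")
  if (!all(dim(true_mask) == dim(pred_edges)))
    stop("shapes differ", call. = FALSE)
  s1 <- sum(true_mask)
  if (s1 == 0) stop("ground truth contains no object", call. = FALSE)
  s2 <- sum(fill_holes(pred_edges))
  (s1 - s2) / s1
}

#' Intersection-over-union of two masks
#'
#' @param a,b Logical matrices of identical shape.
#' @return IoU in \[0, 1\]; defined as 0 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Mask average precision
#'
#' Instance-segmentation AP: predictions are sorted by descending score and
#' greedily matched to unmatched ground-truth masks; a prediction is a true
#' positive when its best IoU with an unmatched truth reaches
#' `iou_threshold`. AP is the all-point-interpolated area under the
#' precision-recall curve. `coco = TRUE` averages AP over IoU thresholds
#' 0.50 to 0.95 in steps of 0.05.
#'
#' @param pred List of predictions, each a list with `mask` (logical
#'   matrix) and `score` in \[0, 1\].
#' @param truth List of ground-truth logical masks.
#' @param iou_threshold Matching threshold; default 0.5.
#' @param coco Average over the COCO threshold grid instead.
#' @return AP in \[0, 1\]. Empty truth with no predictions is defined as
#'   1.0; empty truth with predictions as 0.0.
#' @export
mask_average_precision <- function(pred, truth, iou_threshold = 0.5,
                                   coco = FALSE) {
  if (coco) {
    ths <- seq(0.5, 0.95, by = 0.05)
    return(mean(vapply(ths, function(t)
      mask_average_precision(pred, truth, t, coco = FALSE), numeric(1))))
  }
  if (length(truth) == 0) return(if (length(pred) == 0) 1.0 else 0.0)
  if (length(pred) == 0) return(0.0)
  scores <- vapply(pred, function(p) p$score, numeric(1))
  if (any(scores < 0 | scores > 1)) stop("scores must be in [0,1]", call. = FALSE)
  ord <- order(-scores)
  matched <- rep(FALSE, length(truth))
  tp <- numeric(length(pred))
  for (i in seq_along(ord)) {
    m <- pred[[ord[i]]]$mask
    ious <- vapply(seq_along(truth), function(j)
      if (matched[j]) -1 else mask_iou(m, truth[[j]]), numeric(1))
    j <- which.max(ious)
    if (ious[j] >= iou_threshold) {
      matched[j] <- TRUE
      tp[i] <- 1
    }
  }
  ctp <- cumsum(tp)
  prec <- ctp / seq_along(tp)
  rec <- ctp / length(truth)
  # all-point interpolation: precision envelope from the right
  env <- rev(cummax(rev(prec)))
  sum(diff(c(0, rec)) * env)
}

#' Edge-map metric report
#'
#' Convenience wrapper computing the windowed precision, recall, Dice and
#' Jaccard of a predicted edge map against ground truth, plus (when masks
#' are supplied) the area relative error and mask average precision.
#'
#' @param pred_edges,truth_edges Logical matrices of identical shape.
#' @param truth_masks Optional list of ground-truth instance masks
#'   (full-frame logical matrices); their union is the S1 region.
#' @param pred_masks Optional list of predicted instance masks
#'   (full-frame), each a list with `mask` and `score`, for mask AP.
#' @param window Window size for [windowed_confusion()]; default 3.
#' @param iou_threshold IoU threshold for mask AP; default 0.5.
#' @return List of class `"metric_report"` with `precision`, `recall`,
#'   `dice`, `jaccard`, `area_relative_error`, `mask_ap` (the last two
#'   `NA` when inputs are missing) and the underlying `counts`.
#' @export
edge_metrics <- function(pred_edges, truth_edges, truth_masks = NULL,
                         pred_masks = NULL, window = 3L,
                         iou_threshold = 0.5) {
  counts <- windowed_confusion(pred_edges, truth_edges, window)
  are <- NA_real_
  if (!is.null(truth_masks) && length(truth_masks)) {
    u <- Reduce(`|`, truth_masks)
    are <- area_relative_error(u, pred_edges)
  }
  ap <- NA_real_
  if (!is.null(pred_masks) && !is.null(truth_masks))
    ap <- mask_average_precision(pred_masks, truth_masks, iou_threshold)
  structure(list(precision = precision_score(counts),
                 recall = recall_score(counts),
                 dice = dice_score(counts),
                 jaccard = jaccard_score(counts),
                 area_relative_error = are,
                 mask_ap = ap,
                 counts = counts,
                 window = as.integer(window)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "edge metrics (window %d): P=%.3f R=%.3f Dice=%.3f Jaccard=%.3f\n",
    x$window, x$precision, x$recall, x$dice, x$jaccard))
  if (!is.na(x$area_relative_error))
    cat(sprintf("area relative error: %+.4f\n", x$area_relative_error))
  if (!is.na(x$mask_ap))
    cat(sprintf("mask AP: %.3f\n", x$mask_ap))
  invisible(x)
}

#' Write a metric report as JSON
#'
#' @param report A [edge_metrics()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path) {
  out <- list(precision = report$precision, recall = report$recall,
              dice = report$dice, jaccard = report$jaccard,
              area_relative_error = report$area_relative_error,
              mask_ap = report$mask_ap,
              counts = unclass(report$counts), window = report$window)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}
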