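#' Pairwise intersection-over-union of two box sets
#'
#' Boxes are continuous corner rectangles; IoU is intersection area over
#' union area, 0 for disjoint boxes.
#'
#' @param a,b Data frames with columns `x_min`, `y_min`, `x_max`, `y_max`
#'   (one row per box).
#' @return A `nrow(a) x nrow(b)` numeric matrix of IoU values in `[0, 1]`.
#' @examples
#' b1 <- tibble::tibble(x_min = 0, y_min = 0, x_max = 10, y_max = 10)
#' b2 <- tibble::tibble(x_min = 5, y_min = 0, x_max = 15, y_max = 10)
#' box_iou(b1, b2) # 50 / 150
#' @export
box_iou <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(matrix(numeric(0), nrow = nrow(a), ncol = nrow(b)))
  }
  ix <- pmax(0, outer(a$x_max, b$x_max, pmin) - outer(a$x_min, b$x_min, pmax))
  iy <- pmax(0, outer(a$y_max, b$y_max, pmin) - outer(a$y_min, b$y_min, pmax))
  inter <- ix * iy
  area_a <- (a$x_max - a$x_min) * (a$y_max - a$y_min)
  area_b <- (b$x_max - b$x_min) * (b$y_max - b$y_min)
  inter / (outer(area_a, area_b, `+`) - inter)
}

#' One-to-one Hungarian matching of detections to ground truth
#'
#' Finds the assignment of predictions to ground-truth boxes that maximizes
#' total IoU (via the Hungarian algorithm, [clue::solve_LSAP()]); duplicate
#' predictions on densely packed instances therefore cannot inflate scores
#' the way greedy matching allows. Pairs with zero IoU are dropped from the
#' result — a non-overlapping pair is not a detection of the object. With
#' `class_aware = TRUE` (the default) only same-label pairs are matchable,
#' so a well-localized but misclassified box yields one false positive and
#' one false negative.
#'
#' @param predictions,ground_truth Data frames of boxes; `predictions` needs
#'   a `class` column when `class_aware`, `ground_truth` likewise. Either
#'   may be empty.
#' @param class_aware Restrict matches to identical class labels?
#' @return A list of class `od_match`: `pairs` (tibble with `pred`, `gt`,
#'   `iou` — row indices into the inputs), `unmatched_pred`, `unmatched_gt`,
#'   `n_pred`, `n_gt`.
#' @export
match_boxes <- function(predictions, ground_truth, class_aware = TRUE) {
  n_pred <- nrow(predictions)
  n_gt <- nrow(ground_truth)
  pairs <- tibble::tibble(pred = integer(), gt = integer(), iou = double())
  if (n_pred > 0 && n_gt > 0) {
    iou <- box_iou(predictions, ground_truth)
    if (class_aware) {
      same <- outer(predictions$class, ground_truth$class, `==`)
      iou[!same] <- 0
    }
    # solve_LSAP needs nrow <= ncol; transpose the rectangular case
    if (n_pred <= n_gt) {
      sol <- clue::solve_LSAP(iou, maximum = TRUE)
      pred_idx <- seq_len(n_pred)
      gt_idx <- as.integer(sol)
    } else {
      sol <- clue::solve_LSAP(t(iou), maximum = TRUE)
      gt_idx <- seq_len(n_gt)
      pred_idx <- as.integer(sol)
    }
    ious <- iou[cbind(pred_idx, gt_idx)]
    keep <- ious > 0
    pairs <- tibble::tibble(pred = pred_idx[keep], gt = gt_idx[keep],
                            iou = ious[keep])
  }
  structure(list(pairs = pairs,
                 unmatched_pred = setdiff(seq_len(n_pred), pairs$pred),
                 unmatched_gt = setdiff(seq_len(n_gt), pairs$gt),
                 n_pred = n_pred, n_gt = n_gt),
            class = "od_match")
}

#' Precision, recall and F1 at one IoU threshold
#'
#' A matched pair counts as a true positive when its IoU reaches the
#' threshold; unmatched or sub-threshold predictions are false positives and
#' uncovered ground truths false negatives. F1 is the harmonic mean
#' `2 * P * R / (P + R)`; any zero-denominator case is defined as 0.
#'
#' @param match An `od_match` from [match_boxes()], or a list with elements
#'   `pairs$iou`, `n_pred`, `n_gt` (pooled counts across images work the
#'   same way).
#' @param threshold IoU threshold in (0, 1).
#' @return A one-row tibble with `threshold`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`.
#' @export
prf_at_threshold <- function(match, threshold) {
  stopifnot(threshold > 0, threshold < 1)
  tp <- sum(match$pairs$iou >= threshold)
  fp <- match$n_pred - tp
  fn <- match$n_gt - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  tibble::tibble(threshold = threshold, tp = tp, fp = fp, fn = fn,
                 precision = precision, recall = recall, f1 = f1)
}

#' The 50-point IoU threshold grid
#'
#' 50 evenly spaced thresholds from 0.05 to 0.70 inclusive.
#' @return A numeric vector of length 50.
#' @export
iou_thresholds <- function() seq(0.05, 0.70, length.out = 50)

#' Evaluate detections against a pool
#'
#' Matches detections to ground truth once per image by maximal-total-IoU
#' Hungarian assignment (the match is threshold-independent), then pools
#' true/false positive and false negative counts over all images at each of
#' the 50 IoU thresholds of [iou_thresholds()] and reports per-threshold
#' precision/recall/F1, their mean `mF1`, and the mean IoU of pooled matched
#' pairs with IoU >= 0.5 (`mean_iou_tp50`; defined as 0 when no such pair
#' exists). Micro-averaged: counts, not per-image scores, are pooled.
#'
#' @param detections A detections tibble (columns `image_id`, `class`,
#'   `score`, `x_min`, `y_min`, `x_max`, `y_max`). Every `image_id` must
#'   exist in the pool.
#' @param pool An [od_pool()] providing the ground truth.
#' @param class_aware Passed to [match_boxes()].
#' @return An object of class `od_eval` with elements `curve` (50-row tibble
#'   of per-threshold counts and scores), `mf1`, `mean_iou_tp50`, `tp50`,
#'   `fp50`, `fn50`, `n_pred`, `n_gt`. [tidy()] returns the curve,
#'   [glance()] the one-row summary, and [ggplot2::autoplot()] draws the
#'   threshold sweep.
#' @examples
#' cfg <- fixture_config(n_images = 3, sources = "demo", seed = 1)
#' pool <- generate_dataset(cfg, render = FALSE)$pool
#' dets <- perturb_detections(pool, seed = 1)  # identity corruption
#' glance(evaluate_detections(dets, pool))
#' @export
evaluate_detections <- function(detections, pool, class_aware = TRUE) {
  stopifnot(is_od_pool(pool))
  detections <- as_detections(detections)
  unknown <- setdiff(detections$image_id, pool$images$image_id)
  if (length(unknown) > 0) {
    rlang::abort(paste0("detections for unknown image_id: ",
                        paste(utils::head(unknown, 5), collapse = ", ")))
  }
  ious <- numeric(0)
  n_pred_total <- nrow(detections)
  n_gt_total <- nrow(pool$boxes)
  for (id in unique(c(detections$image_id, pool$boxes$image_id))) {
    m <- match_boxes(detections[detections$image_id == id, ],
                     pool$boxes[pool$boxes$image_id == id, ],
                     class_aware = class_aware)
    ious <- c(ious, m$pairs$iou)
  }
  thresholds <- iou_thresholds()
  pooled <- list(pairs = list(iou = ious), n_pred = n_pred_total,
                 n_gt = n_gt_total)
  curve <- purrr::map_dfr(thresholds, function(t) prf_at_threshold(pooled, t))
  stopifnot(all(diff(curve$f1) <= 1e-12))  # F1 non-increasing along the grid
  tp50 <- sum(ious >= 0.5)
  structure(list(curve = curve,
                 mf1 = mean(curve$f1),
                 mean_iou_tp50 = if (tp50 > 0) mean(ious[ious >= 0.5]) else 0,
                 tp50 = tp50, fp50 = n_pred_total - tp50,
                 fn50 = n_gt_total - tp50,
                 n_pred = n_pred_total, n_gt = n_gt_total,
                 class_aware = class_aware),
            class = "od_eval")
}

#' @export
print.od_eval <- function(x, ...) {
  cat("<od_eval> ", x$n_pred, " detections vs ", x$n_gt, " ground truths (",
      if (x$class_aware) "class-aware" else "class-agnostic", ")\n", sep = "")
  cat(sprintf("  mF1 [0.05:0.70] = %.4f   Mean IoU (TP@0.5) = %.4f\n",
              x$mf1, x$mean_iou_tp50))
  cat(sprintf("  at IoU 0.5: TP %d, FP %d, FN %d\n", x$tp50, x$fp50, x$fn50))
  invisible(x)
}

#' @export
tidy.od_eval <- function(x, ...) x$curve

#' @export
glance.od_eval <- function(x, ...) {
  tibble::tibble(mf1 = x$mf1, mean_iou_tp50 = x$mean_iou_tp50,
                 tp50 = x$tp50, fp50 = x$fp50, fn50 = x$fn50,
                 n_pred = x$n_pred, n_gt = x$n_gt)
}

#' @export
autoplot.od_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(object$curve,
                              c("precision", "recall", "f1"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$mf1, linetype = "dashed") +
    ggplot2::labs(x = "IoU threshold", y = NULL,
                  title = sprintf("mF1 = %.3f, Mean IoU (TP@0.5) = %.3f",
                                  object$mf1, object$mean_iou_tp50)) +
    ggplot2::ylim(0, 1)
}

#' Non-maximum suppression
#'
#' Removes detections scoring below `score_threshold`, then processes the
#' rest in descending score order (stable: ties keep input order),
#' suppressing any detection whose IoU with an already-kept detection *of
#' the same class* exceeds `iou_threshold`. Defaults follow the common
#' open-vocabulary detector post-processing operating point (score 0.05,
#' IoU 0.50).
#'
#' @param detections A detections tibble.
#' @param iou_threshold Suppression IoU threshold in `[0, 1]`.
#' @param score_threshold Minimum score kept, in `[0, 1]`.
#' @return The surviving detections, in the original input order.
#' @export
nms <- function(detections, iou_threshold = 0.5, score_threshold = 0.05) {
  stopifnot(iou_threshold >= 0, iou_threshold <= 1,
            score_threshold >= 0, score_threshold <= 1)
  detections <- as_detections(detections)
  detections <- detections[detections$score >= score_threshold, ]
  if (nrow(detections) <= 1) return(detections)
  ord <- order(-detections$score)  # stable for ties
  keep <- logical(nrow(detections))
  iou <- box_iou(detections, detections)
  for (i in ord) {
    prior <- which(keep & detections$class == detections$class[i])
    if (!any(iou[i, prior] > iou_threshold)) keep[i] <- TRUE
  }
  detections[keep, ]
}
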