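box <- function(x0, y0, x1, y1, class = "c", score = 0.9, id = "img") {
  tibble::tibble(image_id = id, class = class, score = score,
                 x_min = x0, y_min = y0, x_max = x1, y_max = y1)
}

test_that("IoU follows area arithmetic", {
  a <- box(0, 0, 10, 10)
  expect_equal(box_iou(a, a)[1, 1], 1)
  expect_equal(box_iou(a, box(20, 20, 30, 30))[1, 1], 0)
  expect_equal(box_iou(a, box(5, 0, 15, 10))[1, 1], 50 / 150)
  # touching edges share no area
  expect_equal(box_iou(a, box(10, 0, 20, 10))[1, 1], 0)
  m <- box_iou(dplyr::bind_rows(a, box(5, 0, 15, 10)),
               dplyr::bind_rows(a, box(20, 20, 30, 30)))
  expect_equal(dim(m), c(2, 2))
})

test_that("Hungarian matching is optimal, not greedy", {
  # IoU matrix [[0.6, 0.5], [0.5, 0.1]]: greedy takes 0.6 + 0.1 = 0.7,
  # optimal crosses for 0.5 + 0.5 = 1.0
  pred <- dplyr::bind_rows(box(0, 0, 12, 10), box(0, 12, 10, 22))
  gt <- dplyr::bind_rows(box(0, 0, 10, 15), box(0, 4, 10, 24))
  iou <- box_iou(pred, gt)
  m <- match_boxes(pred, gt)
  expect_equal(sum(m$pairs$iou), brute_force_match_total(iou),
               tolerance = 1e-12)
  expect_equal(nrow(m$pairs), 2)

  # empty predictions leave every ground truth unmatched
  m0 <- match_boxes(pred[0, ], gt)
  expect_equal(nrow(m0$pairs), 0)
  expect_equal(m0$unmatched_gt, 1:2)

  # zero-IoU pairs are dropped even when assigned
  m1 <- match_boxes(box(0, 0, 5, 5), box(50, 50, 60, 60))
  expect_equal(nrow(m1$pairs), 0)
  expect_equal(m1$unmatched_pred, 1)
})

test_that("Hungarian total equals the brute-force permutation maximum", {
  for (seed in 1:40) {
    n <- withr::with_seed(seed, sample(1:6, 2, replace = TRUE))
    pred <- random_boxes(n[1], seed = seed * 2)
    gt <- random_boxes(n[2], seed = seed * 2 + 1)
    m <- match_boxes(pred, gt, class_aware = FALSE)
    expect_equal(sum(m$pairs$iou), brute_force_match_total(box_iou(pred, gt)),
                 tolerance = 1e-9)
  }
})

test_that("class-aware matching restricts pairs to identical labels", {
  pred <- box(0, 0, 10, 10, class = "a")
  gt <- box(0, 0, 10, 10, class = "b")
  expect_equal(nrow(match_boxes(pred, gt, class_aware = TRUE)$pairs), 0)
  expect_equal(nrow(match_boxes(pred, gt, class_aware = FALSE)$pairs), 1)
})

test_that("precision/recall/F1 follow the counting definitions", {
  pred <- dplyr::bind_rows(box(0, 0, 10, 10), box(20, 20, 30, 30))
  m <- match_boxes(pred, pred)
  expect_equal(unlist(prf_at_threshold(m, 0.5)[, c("precision", "recall",
                                                   "f1")]),
               c(precision = 1, recall = 1, f1 = 1))
  # no predictions
  m0 <- match_boxes(pred[0, ], pred)
  expect_equal(unlist(prf_at_threshold(m0, 0.5)[, c("precision", "recall",
                                                    "f1")]),
               c(precision = 0, recall = 0, f1 = 0))
  # 1 pair at IoU 0.8 with n_pred 1, n_gt 2
  fake <- list(pairs = list(iou = 0.8), n_pred = 1, n_gt = 2)
  out <- prf_at_threshold(fake, 0.5)
  expect_equal(out$precision, 1)
  expect_equal(out$recall, 0.5)
  expect_equal(out$f1, 2 / 3)
})

test_that("the threshold grid has 50 even steps from 0.05 to 0.70", {
  t <- iou_thresholds()
  expect_length(t, 50)
  expect_equal(t[1], 0.05)
  expect_equal(t[50], 0.70)
  expect_equal(unique(round(diff(t), 12)), round(0.65 / 49, 12))
})

test_that("evaluation pools counts and reports mF1 and TP@0.5 mean IoU", {
  # identity: detections equal to ground truth
  pool <- random_pool(4, seed = 5)
  det <- perturb_detections(pool, seed = 1)
  ev <- evaluate_detections(det, pool)
  expect_equal(ev$mf1, 1)
  expect_equal(ev$mean_iou_tp50, 1)

  # worked example: one prediction overlapping one of 2 GT at IoU 0.8
  imgs <- tibble::tibble(image_id = "a", source = "s",
                         width = 100L, height = 100L)
  gt <- dplyr::bind_rows(box(0, 0, 10, 10, id = "a"),
                         box(50, 50, 60, 60, id = "a"))
  pool1 <- od_pool(imgs, gt[, setdiff(names(gt), "score")])
  pred <- box(0, 0, 10, 8, id = "a")  # IoU 80/100 = 0.8 with the first GT
  ev <- evaluate_detections(pred, pool1)
  expect_true(all(abs(ev$curve$f1 - 2 / 3) < 1e-12))
  expect_equal(ev$mf1, 2 / 3, tolerance = 1e-9)
  expect_equal(ev$mean_iou_tp50, 0.8)

  # no true positive at 0.5 -> mean IoU defined as 0
  weak <- box(0, 0, 30, 30, id = "a")  # IoU with GT1 = 100/900
  ev <- evaluate_detections(weak, pool1)
  expect_equal(ev$mean_iou_tp50, 0)
  expect_gt(ev$curve$f1[1], 0)  # still a coarse-localization hit at 0.05

  # unknown image id is a validation error
  expect_error(evaluate_detections(box(0, 0, 5, 5, id = "zzz"), pool1),
               "unknown image_id")
})

test_that("F1 is non-increasing along the grid and mF1 in [0,1]", {
  pool <- random_pool(5, seed = 11)
  for (seed in 1:10) {
    det <- perturb_detections(pool, jitter_sd = seed / 3, drop_rate = 0.2,
                              fp_rate = 1, label_flip_rate = 0.1,
                              seed = seed)
    ev <- evaluate_detections(det, pool)
    expect_true(all(diff(ev$curve$f1) <= 1e-12))
    expect_gte(ev$mf1, 0)
    expect_lte(ev$mf1, 1)
    if (ev$mean_iou_tp50 > 0) expect_gte(ev$mean_iou_tp50, 0.5)
  }
})

test_that("a spurious detection never increases precision", {
  pool <- random_pool(3, seed = 21)
  det <- perturb_detections(pool, jitter_sd = 2, seed = 2)
  base <- evaluate_detections(det, pool)
  spur <- dplyr::bind_rows(det, box(900, 900, 950, 950,
                                    class = pool$classes[1],
                                    id = pool$images$image_id[1]))
  worse <- evaluate_detections(spur, pool)
  expect_true(all(worse$curve$precision <= base$curve$precision + 1e-12))
})

test_that("NMS suppresses same-class overlaps in score order", {
  # two identical boxes: higher score survives
  d <- dplyr::bind_rows(box(0, 0, 10, 10, score = 0.9),
                        box(0, 0, 10, 10, score = 0.8))
  kept <- nms(d)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$score, 0.9)

  # disjoint boxes all survive
  d <- dplyr::bind_rows(box(0, 0, 10, 10), box(20, 0, 30, 10),
                        box(40, 0, 50, 10))
  expect_equal(nrow(nms(d)), 3)

  # different classes never suppress each other
  d <- dplyr::bind_rows(box(0, 0, 10, 10, class = "a", score = 0.9),
                        box(0, 0, 10, 10, class = "b", score = 0.8))
  expect_equal(nrow(nms(d)), 2)

  # score threshold removes low-confidence detections first
  d <- dplyr::bind_rows(box(0, 0, 10, 10, score = 0.9),
                        box(40, 40, 50, 50, score = 0.01))
  expect_equal(nrow(nms(d, score_threshold = 0.05)), 1)

  # five hand-placed boxes checked against direct rule application:
  # b2 overlaps b1 (IoU 81/119 > 0.5, suppressed); b3 overlaps b1 at
  # 64/136 < 0.5 (kept); b4 disjoint (kept); b5 overlaps b3 heavily but
  # scores higher, so b5 is processed first and b3 is suppressed instead
  d <- dplyr::bind_rows(
    b1 = box(0, 0, 10, 10, score = 0.95),
    b2 = box(1, 1, 11, 11, score = 0.90),
    b3 = box(2, 2, 12, 12, score = 0.50),
    b4 = box(30, 30, 40, 40, score = 0.40),
    b5 = box(2.5, 2.5, 12.5, 12.5, score = 0.60))
  kept <- nms(d, iou_threshold = 0.5)
  expect_equal(kept$score, c(0.95, 0.40, 0.60))
})
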