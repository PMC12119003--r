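# Detection metrics against hand-worked examples and independent oracles.

test_that("IoU handles the standard rectangle cases", {
  expect_equal(iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 0, 3, 2)), 1 / 3)
  expect_equal(iou(c(1, 1, 1, 3), c(0, 0, 2, 2)), 0)  # degenerate box
})

test_that("greedy matching follows the single-match and class rules", {
  gt <- data.frame(class_id = 0L, x1 = 0, y1 = 0, x2 = 10, y2 = 10)
  p1 <- data.frame(class_id = 0L, conf = 0.9, x1 = 0, y1 = 0, x2 = 10, y2 = 10)
  m <- match_detections(p1, gt, 0.5)
  expect_equal(unlist(m$counts[, c("TP", "FP", "FN")]),
               c(TP = 1L, FP = 0L, FN = 0L))
  # two predictions on one gt: the higher confidence wins
  p2 <- rbind(p1, data.frame(class_id = 0L, conf = 0.7, x1 = 1, y1 = 1,
                             x2 = 11, y2 = 11))
  m2 <- match_detections(p2, gt, 0.5)
  expect_equal(unlist(m2$counts[, c("TP", "FP", "FN")]),
               c(TP = 1L, FP = 1L, FN = 0L))
  expect_true(m2$tp_flags[1] && !m2$tp_flags[2])
  # wrong class over the same box: FP and FN
  p3 <- data.frame(class_id = 1L, conf = 0.9, x1 = 0, y1 = 0, x2 = 10, y2 = 10)
  m3 <- match_detections(p3, gt, 0.5)
  expect_equal(sum(m3$counts$FP), 1)
  expect_equal(sum(m3$counts$FN), 1)
})

test_that("precision/recall formulas and zero conventions hold", {
  expect_equal(precision(data.frame(TP = 3, FP = 1, FN = 0)), 0.75)
  expect_equal(recall(data.frame(TP = 3, FP = 0, FN = 3)), 0.5)
  expect_equal(precision(data.frame(TP = 0, FP = 0, FN = 2)), 1)
  expect_equal(recall(data.frame(TP = 0, FP = 1, FN = 0)), 1)
})

test_that("average precision matches the all-cutoff brute-force oracle", {
  gt <- data.frame(class_id = 0L,
                   x1 = c(0, 20), y1 = c(0, 20), x2 = c(10, 30), y2 = c(10, 30))
  # 3 predictions, mixed correctness, fixed confidences
  preds <- data.frame(class_id = 0L, conf = c(0.9, 0.8, 0.6),
                      x1 = c(0, 50, 21), y1 = c(0, 50, 19),
                      x2 = c(10, 60, 31), y2 = c(10, 60, 29))
  got <- average_precision(preds, gt, 0.5)
  want <- oracle_ap_all_cutoffs(preds, gt, 0.5)
  expect_equal(got, want, tolerance = 1e-9)
  # degenerate cases
  expect_equal(average_precision(preds[0, ], gt, 0.5), 0)
  one <- data.frame(class_id = 0L, conf = 0.99, x1 = 0, y1 = 0, x2 = 10,
                    y2 = 10)
  expect_equal(average_precision(one, gt[1, ], 0.5), 1)
  # AP is invariant to strictly monotone confidence transformations
  preds2 <- preds
  preds2$conf <- plogis(5 * preds$conf - 2)
  expect_equal(average_precision(preds2, gt, 0.5), got)
})

test_that("metrics agree with an independent COCO-style oracle on random fixtures", {
  for (seed in c(101, 202, 303, 404)) {
    fx <- random_fixture(seed)
    if (!nrow(fx$gts)) next
    got <- map_at(fx$preds, fx$gts, fx$nc, 0.5)
    want <- oracle_map(fx$preds, fx$gts, fx$nc, 0.5)
    expect_lt(abs(got - want), 0.01)
  }
})

test_that("TP + FN equals the ground-truth count per class and threshold", {
  for (seed in c(11, 22)) {
    fx <- random_fixture(seed)
    for (thr in c(0.3, 0.5, 0.75)) {
      m <- match_detections(fx$preds, fx$gts, thr)
      for (cl in unique(fx$gts$class_id)) {
        row <- m$counts[m$counts$class_id == cl, ]
        expect_equal(row$TP + row$FN, sum(fx$gts$class_id == cl))
      }
    }
  }
})

test_that("mAP50:95 never exceeds mAP50 on random fixtures", {
  for (seed in c(7, 77, 777)) {
    fx <- random_fixture(seed)
    if (!nrow(fx$gts)) next
    m50 <- map_at(fx$preds, fx$gts, fx$nc, 0.5)
    m5095 <- map50_95(fx$preds, fx$gts, fx$nc)
    expect_lte(m5095, m50 + 1e-12)
  }
})

test_that("confusion matrices place matches, FPs and FNs correctly", {
  # perfect single-class predictions: diagonal only
  gt <- data.frame(class_id = c(0L, 0L), x1 = c(0, 20), y1 = c(0, 20),
                   x2 = c(10, 30), y2 = c(10, 30))
  pd <- data.frame(class_id = c(0L, 0L), conf = c(0.9, 0.8),
                   x1 = c(0, 20), y1 = c(0, 20), x2 = c(10, 30),
                   y2 = c(10, 30))
  cm <- confusion_matrix(pd, gt, num_classes = 2)
  expect_equal(cm[1, 1], 2L)
  expect_equal(sum(cm) - cm[1, 1], 0L)
  # all predictions below the confidence threshold: only the background row
  pd2 <- transform(pd, conf = 0.1)
  cm2 <- confusion_matrix(pd2, gt, num_classes = 2, conf_thr = 0.25)
  expect_equal(sum(cm2[1:2, ]), 0L)
  expect_equal(cm2[3, 1], 2L)
  # crafted 4-object case, enumerated by hand:
  #   gt: class0 @(0,0,10,10), class1 @(20,20,30,30), class1 @(50,50,60,60),
  #       class0 @(80,80,90,90)
  #   preds: class0 on gt1 (match, diag), class0 on gt2 (cross-class cell),
  #          class1 in empty space (pred-background), nothing on gt3/gt4
  #          (two background-true entries)
  gt4 <- data.frame(class_id = c(0L, 1L, 1L, 0L),
                    x1 = c(0, 20, 50, 80), y1 = c(0, 20, 50, 80),
                    x2 = c(10, 30, 60, 90), y2 = c(10, 30, 60, 90))
  pd4 <- data.frame(class_id = c(0L, 0L, 1L), conf = c(0.9, 0.8, 0.7),
                    x1 = c(0, 20, 200), y1 = c(0, 20, 200),
                    x2 = c(10, 30, 210), y2 = c(10, 30, 210))
  cm4 <- confusion_matrix(pd4, gt4, num_classes = 2)
  want <- matrix(0L, 3, 3)
  want[1, 1] <- 1L  # class0 matched class0
  want[1, 2] <- 1L  # class0 prediction matched class1 gt
  want[2, 3] <- 1L  # class1 prediction unmatched -> background column
  want[3, 1] <- 1L  # class0 gt missed
  want[3, 2] <- 1L  # class1 gt missed
  expect_equal(unname(cm4), want)
})

test_that("the per-class summary carries the report schema", {
  fx <- random_fixture(55)
  s <- eval_summary(fx$preds, fx$gts, fx$nc)
  expect_equal(names(s$table),
               c("Class", "Instances", "P", "R", "mAP50", "mAP50_95"))
  expect_equal(s$table$Class[1], "all")
  vals <- unlist(s$table[, c("P", "R", "mAP50", "mAP50_95")])
  expect_true(all(is.na(vals) | (vals >= 0 & vals <= 1)))
  path <- tempfile(fileext = ".csv")
  write_eval_csv(s, path)
  expect_true(file.exists(path))
  expect_equal(names(utils::read.csv(path, check.names = FALSE))[1:2],
               c("Class", "Instances"))
  unlink(path)
})
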