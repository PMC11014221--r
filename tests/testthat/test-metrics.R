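counts_of <- function(tp, fp, fn, tn = 0) list(TP = tp, FP = fp, FN = fn, TN = tn)

test_that("windowed confusion handles the degenerate and identical cases", {
  empty <- matrix(FALSE, 8, 9)
  c0 <- windowed_confusion(empty, empty, 3)
  expect_equal(unclass(c0)[c("TP", "FP", "FN", "TN")],
               list(TP = 0L, FP = 0L, FN = 0L, TN = 72L))
  set.seed(61)
  e <- random_mask(10, 10, 0.15)
  ci <- windowed_confusion(e, e, 3)
  expect_equal(ci$FP, 0L)
  expect_equal(ci$FN, 0L)
  expect_equal(ci$TP + ci$TN, 100L)
})

test_that("windowed confusion matches the brute-force sliding-window oracle", {
  # one-pixel offset: neighbourhoods still overlap under a 3x3 window
  p <- matrix(FALSE, 11, 11); p[6, 7] <- TRUE
  t <- matrix(FALSE, 11, 11); t[6, 6] <- TRUE
  got <- windowed_confusion(p, t, 3)
  want <- oracle_confusion(p, t, 3)
  expect_equal(unclass(got)[c("TP", "FP", "FN", "TN")], want)
  expect_gt(got$TP, 0)
  set.seed(62)
  for (i in 1:8) {
    pr <- random_mask(9, 13, 0.2); tr <- random_mask(9, 13, 0.2)
    for (w in c(1, 3, 5)) {
      got <- windowed_confusion(pr, tr, w)
      expect_equal(unclass(got)[c("TP", "FP", "FN", "TN")],
                   oracle_confusion(pr, tr, w))
    }
  }
})

test_that("window 1 reduces to the pixelwise confusion matrix", {
  set.seed(63)
  p <- random_mask(12, 12, 0.3); t <- random_mask(12, 12, 0.3)
  c1 <- windowed_confusion(p, t, 1)
  expect_equal(c1$TP, sum(p & t))
  expect_equal(c1$FP, sum(p & !t))
  expect_equal(c1$FN, sum(!p & t))
})

test_that("enlarging the window never decreases TP", {
  set.seed(64)
  p <- random_mask(15, 15, 0.1); t <- random_mask(15, 15, 0.1)
  tps <- vapply(c(1, 3, 5, 7), function(w) windowed_confusion(p, t, w)$TP, numeric(1))
  expect_true(all(diff(tps) >= 0))
})

test_that("the four rate formulas give the printed arithmetic", {
  cts <- counts_of(826, 174, 49)
  expect_equal(precision_score(cts), 0.826)
  expect_equal(recall_score(cts), 826 / 875, tolerance = 1e-12)
  expect_equal(dice_score(cts), 1652 / 1875, tolerance = 1e-12)
  expect_equal(jaccard_score(cts), 826 / 1049, tolerance = 1e-12)
  # all-background prediction on a nonempty truth
  z <- counts_of(0, 3, 5)
  expect_equal(dice_score(z), 0)
  expect_equal(jaccard_score(z), 0)
})

test_that("zero denominators yield NA with a warning", {
  expect_warning(p <- precision_score(counts_of(0, 0, 4)), "undefined")
  expect_true(is.na(p))
  expect_warning(r <- recall_score(counts_of(0, 5, 0)), "undefined")
  expect_true(is.na(r))
})

test_that("Dice and Jaccard satisfy their precision/recall identities", {
  set.seed(65)
  for (i in 1:25) {
    cts <- counts_of(sample(1:500, 1), sample(0:200, 1), sample(0:200, 1))
    p <- precision_score(cts); r <- recall_score(cts)
    expect_equal(dice_score(cts), dice_from_rates(p, r), tolerance = 1e-12)
    expect_equal(jaccard_score(cts), jaccard_from_rates(p, r), tolerance = 1e-12)
    # and Dice = 2J/(1+J)
    j <- jaccard_score(cts)
    expect_equal(dice_score(cts), 2 * j / (1 + j), tolerance = 1e-12)
  }
  # the identities work on the percent scale too
  expect_equal(dice_from_rates(88.3, 93.6), 90.9, tolerance = 0.05)
  expect_equal(jaccard_from_rates(88.3, 93.6), 83.3, tolerance = 0.05)
})

test_that("windowed Dice is symmetric in pred and truth", {
  set.seed(66)
  p <- random_mask(14, 14, 0.15); t <- random_mask(14, 14, 0.15)
  expect_equal(dice_score(windowed_confusion(p, t, 3)),
               dice_score(windowed_confusion(t, p, 3)), tolerance = 1e-12)
})

test_that("area relative error follows the signed S1/S2 convention", {
  solid <- matrix(FALSE, 30, 30); solid[6:25, 6:25] <- TRUE
  # a perfect contour encloses exactly the truth
  expect_equal(area_relative_error(solid, mask_contour(solid)), 0)
  # S1 = 400, S2 = 324 -> +0.19
  smaller <- matrix(FALSE, 30, 30); smaller[7:24, 7:24] <- TRUE
  expect_equal(area_relative_error(solid, mask_contour(smaller)),
               (400 - 324) / 400)
  # an over-large contour gives a negative error
  bigger <- matrix(FALSE, 30, 30); bigger[4:27, 4:27] <- TRUE
  expect_lt(area_relative_error(solid, mask_contour(bigger)), 0)
  expect_error(area_relative_error(matrix(FALSE, 5, 5), matrix(FALSE, 5, 5)),
               "no object")
})

test_that("mask AP handles the canonical cases", {
  truth <- list(disk_mask(20, 20, 10, 10, 5))
  perfect <- list(list(mask = truth[[1]], score = 0.9))
  expect_equal(mask_average_precision(perfect, truth), 1.0)
  expect_equal(mask_average_precision(list(), truth), 0.0)
  expect_equal(mask_average_precision(list(), list()), 1.0)
  expect_equal(mask_average_precision(perfect, list()), 0.0)
  # a spurious lower-scored detection does not hurt AP...
  spurious <- list(mask = disk_mask(20, 20, 4, 16, 2), score = 0.1)
  expect_equal(mask_average_precision(c(perfect, list(spurious)), truth), 1.0)
  # ...but a spurious higher-scored one halves it (two-point PR curve)
  spurious_hi <- list(mask = disk_mask(20, 20, 4, 16, 2), score = 0.95)
  expect_equal(mask_average_precision(c(perfect, list(spurious_hi)), truth), 0.5)
})

test_that("COCO-style averaging over IoU thresholds is the mean of per-threshold APs", {
  truth <- list(disk_mask(30, 30, 15, 15, 8))
  # a prediction with IoU about 0.7: matched at low thresholds only
  pred <- list(list(mask = disk_mask(30, 30, 15, 17, 8), score = 1))
  per <- vapply(seq(0.5, 0.95, 0.05), function(t)
    mask_average_precision(pred, truth, t), numeric(1))
  expect_equal(mask_average_precision(pred, truth, coco = TRUE), mean(per))
  expect_true(any(per == 1) && any(per == 0))
})

test_that("edge_metrics bundles the report and writes valid JSON", {
  disk <- disk_mask(40, 40, 20, 20, 12)
  rep <- edge_metrics(mask_contour(disk), mask_contour(disk),
                      truth_masks = list(disk),
                      pred_masks = list(list(mask = disk, score = 1)))
  expect_equal(rep$dice, 1)
  expect_equal(rep$area_relative_error, 0)
  expect_equal(rep$mask_ap, 1)
  path <- tempfile(fileext = ".json")
  write_metric_report(rep, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$precision, 1)
  expect_equal(back$counts$TN + back$counts$TP, 1600)
})
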