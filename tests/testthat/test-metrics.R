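test_that("confusion counts pixels with foreground as the positive class", {
  gt <- matrix(0L, 3, 3); gt[1:4] <- 1L
  c1 <- confusion(gt, gt)
  expect_equal(unlist(c1[c("TP", "FP", "FN", "TN")]), c(TP = 4, FP = 0, FN = 0, TN = 5))

  comp <- 1L - gt
  c2 <- confusion(comp, gt)
  expect_equal(c2$TP, 0)
  expect_equal(c2$TP + c2$FP + c2$FN + c2$TN, 9)

  z <- matrix(0L, 3, 3)
  c3 <- confusion(z, z)
  expect_equal(unlist(c3[c("TP", "FP", "FN", "TN")]), c(TP = 0, FP = 0, FN = 0, TN = 9))
  expect_error(confusion(z, matrix(0L, 2, 2)), "shapes")
})

test_that("precision/recall/F1, Dice and Jaccard match hand arithmetic", {
  c0 <- cimtseg:::counts(TP = 2, FP = 1, FN = 2, TN = 5)
  prf <- precision_recall_f1(c0)
  expect_equal(prf[["precision"]], 2 / 3)
  expect_equal(prf[["recall"]], 1 / 2)
  expect_equal(prf[["f1"]], 4 / 7)
  expect_equal(dice(c0), 4 / 7)
  expect_equal(jaccard(c0), 2 / 5)

  perfect <- cimtseg:::counts(TP = 10, FP = 0, FN = 0, TN = 5)
  expect_equal(unname(precision_recall_f1(perfect)), c(1, 1, 1))
  expect_equal(dice(perfect), 1)

  # published P/R give this F1 under pooled arithmetic
  p <- 0.8118; r <- 0.8206
  expect_equal(round(2 * p * r / (p + r), 4), 0.8162)

  # degenerate conventions
  empty <- cimtseg:::counts(0, 0, 0, 9)
  expect_equal(unname(precision_recall_f1(empty)), c(0, 0, 0))
  expect_equal(dice(empty), 1)
  expect_equal(jaccard(empty), 1)
})

test_that("metrics agree with the set-operation oracle on random masks", {
  set.seed(41)
  for (i in 1:50) {
    pred <- random_mask(16, 16, runif(1, 0, 0.6))
    gt <- random_mask(16, 16, runif(1, 0, 0.6))
    o <- oracle_metrics(pred, gt)
    cc <- confusion(pred, gt)
    prf <- precision_recall_f1(cc)
    expect_equal(prf[["precision"]], o$precision)
    expect_equal(prf[["recall"]], o$recall)
    expect_equal(prf[["f1"]], o$f1)
    expect_equal(dice(cc), o$dice)
    expect_equal(jaccard(cc), o$jaccard)
    # symmetry of the overlap measures
    expect_equal(dice(confusion(gt, pred)), o$dice)
    expect_equal(jaccard(confusion(gt, pred)), o$jaccard)
  }
})

test_that("evaluate_set distinguishes macro and micro averaging", {
  # single image: macro = micro
  set.seed(42)
  pred <- random_mask(10, 10); gt <- random_mask(10, 10)
  ma <- evaluate_set(list(pred), list(gt), "macro")
  mi <- evaluate_set(list(pred), list(gt), "micro")
  for (f in c("precision", "recall", "f1", "dice", "jaccard"))
    expect_equal(ma[[f]], mi[[f]])

  # two images with Dice 1 and 0 (equal foreground sizes): macro Dice 0.5
  a <- matrix(0L, 4, 4); a[1:2, 1] <- 1L
  b <- matrix(0L, 4, 4); b[1:2, 2] <- 1L
  rep2 <- evaluate_set(list(a, b), list(a, a), "macro")
  expect_equal(rep2$dice, 0.5)

  # micro F1 == micro Dice exactly, for any set
  for (i in 1:10) {
    preds <- lapply(1:4, function(j) random_mask(8, 12, runif(1, 0.1, 0.5)))
    gts <- lapply(1:4, function(j) random_mask(8, 12, runif(1, 0.1, 0.5)))
    mic <- evaluate_set(preds, gts, "micro")
    expect_identical(mic$f1, mic$dice)
    # pooled Jaccard identity J = D / (2 - D)
    expect_equal(mic$jaccard, mic$dice / (2 - mic$dice))
  }
  expect_error(evaluate_set(list(a), list(a, b)), "lengths")
})
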