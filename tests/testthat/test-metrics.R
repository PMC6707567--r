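# Dice, confusion-matrix battery, mean IOU, AUC.

test_that("dice coefficient and loss follow the overlap formula", {
  x <- matrix(c(1, 1, 1, 1), 2)
  y <- matrix(c(1, 0, 0, 0), 2)
  expect_equal(dice_coefficient(x, y, smooth = 0), 0.4)  # 2*1/(4+1)
  expect_equal(dice_loss(x, y, smooth = 0), 0.6)
  expect_equal(dice_coefficient(x, x), 1)  # identical masks: exact even smoothed
  expect_equal(dice_coefficient(x, x, smooth = 0), 1)
  # disjoint masks: exactly s / (|X| + |Y| + s)
  a <- matrix(c(1, 0, 0, 0), 2); b <- matrix(c(0, 1, 0, 0), 2)
  expect_equal(dice_coefficient(a, b, smooth = 1), 1 / 3)
  expect_equal(dice_loss(a, b, smooth = 1) + dice_coefficient(a, b, smooth = 1), 1)
  expect_error(dice_coefficient(x, matrix(0, 3, 3)), "differ")
  # symmetry
  set.seed(20)
  for (i in 1:10) {
    m1 <- matrix(rbinom(64, 1, 0.4), 8)
    m2 <- matrix(rbinom(64, 1, 0.4), 8)
    expect_equal(dice_coefficient(m1, m2), dice_coefficient(m2, m1))
  }
})

test_that("confusion counts and scalar metrics match hand counts", {
  gold <- matrix(0, 3, 3); gold[1:2, 1:2] <- 1          # 4 lesion pixels
  pred <- gold; pred[2, 2] <- 0; pred[3, 3] <- 1        # miss 1, spurious 1
  cts <- confusion(gold, pred)
  expect_equal(cts, list(tp = 3, fp = 1, fn = 1, tn = 4))
  sm <- scalar_metrics(cts)
  expect_equal(sm$acc, 7 / 9)
  expect_equal(sm$pc, 3 / 4)
  expect_equal(sm$sen, 3 / 4)
  expect_equal(sm$sp, 4 / 5)
  expect_equal(sm$f1, 3 / 4)
  expect_equal(with(cts, tp + fp + fn + tn), 9)
  expect_error(confusion(gold, pred * 0.5), "binary")
  # degenerate conventions
  all1 <- scalar_metrics(list(tp = 9, fp = 0, fn = 0, tn = 0))
  expect_true(all(unlist(all1[c("acc", "pc", "sen", "f1")]) == 1))
  none <- scalar_metrics(list(tp = 0, fp = 0, fn = 5, tn = 4))
  expect_equal(none$pc, 0)
  expect_equal(none$f1, 0)
})

test_that("scalar metrics agree with the per-pixel loop oracle on random masks", {
  set.seed(21)
  for (i in 1:100) {
    gold <- matrix(rbinom(256, 1, runif(1, 0.2, 0.8)), 16)
    pred <- matrix(rbinom(256, 1, runif(1, 0.2, 0.8)), 16)
    o <- oracle_metrics(gold, pred)
    cts <- confusion(gold, pred)
    sm <- scalar_metrics(cts)
    expect_equal(unlist(cts), unlist(o[c("tp", "fp", "fn", "tn")]))
    expect_equal(unlist(sm), unlist(o[c("acc", "pc", "sen", "sp", "f1")]))
    expect_equal(dice_coefficient(gold, pred, smooth = 0),
                 o$dice, tolerance = 1e-12)
    expect_equal(mean_iou(gold, pred), o$iou)
    # DC and IOU identity: IOU <= DC <= 2*IOU/(1+IOU)
    if (o$iou > 0) {
      expect_lte(o$iou, o$dice + 1e-12)
      expect_lte(o$dice, 2 * o$iou / (1 + o$iou) + 1e-12)
    }
  }
})

test_that("mean IOU averages per-pair lesion IOU", {
  full <- matrix(1, 2, 2)
  half <- matrix(c(1, 1, 0, 0), 2)
  expect_equal(mean_iou(list(full), list(full)), 1)
  expect_equal(mean_iou(list(full, full), list(full, half)), 0.75)
  expect_error(mean_iou(list(), list()), "empty")
})

test_that("AUC matches the exhaustive threshold sweep", {
  gold <- matrix(c(1, 1, 1, 0, 0, 0, 1, 0), 2)
  prob <- matrix(c(0.9, 0.8, 0.4, 0.3, 0.2, 0.35, 0.55, 0.1), 2)
  got <- auc_curves(list(gold), list(prob))
  ref <- oracle_auc(gold, prob)
  expect_equal(got$roc_auc, ref$roc, tolerance = 1e-12)
  expect_equal(got$pr_auc, ref$pr, tolerance = 1e-12)
  # perfect prediction and uninformative prediction
  expect_equal(auc_curves(list(gold), list(gold))$roc_auc, 1)
  expect_equal(auc_curves(list(gold), list(gold * 0 + 0.5))$roc_auc, 0.5)
  expect_error(auc_curves(list(gold * 0 + 1), list(prob)), "single class")
  set.seed(22)
  for (i in 1:10) {
    g <- matrix(rbinom(36, 1, 0.5), 6)
    if (all(g == 0) || all(g == 1)) next
    p <- matrix(runif(36), 6)
    expect_equal(auc_curves(list(g), list(p))$roc_auc, oracle_auc(g, p)$roc)
  }
})

test_that("metrics_report assembles the nine-score battery consistently", {
  set.seed(23)
  gold <- lapply(1:4, function(i) matrix(rbinom(64, 1, 0.3), 8))
  prob <- lapply(1:4, function(i) matrix(runif(64), 8))
  rep <- metrics_report(gold, prob, threshold = 0.5)
  expect_identical(names(rep)[1:9],
                   c("Loss", "Acc", "DC", "Sen", "Sp", "F1", "Pc", "M-IOU", "AUC"))
  expect_true(all(unlist(rep) >= 0 & unlist(rep) <= 1))
  # aggregate row is reproducible from the exported confusion totals
  cts <- attr(rep, "confusion")
  sm <- scalar_metrics(cts)
  expect_equal(rep$Acc, sm$acc)
  expect_equal(rep$F1, sm$f1)
  # perfect oracle predictions: DC = 1, loss ~ 0 (smoothing aside)
  perf <- metrics_report(gold, gold)
  expect_equal(perf$DC, 1)
  expect_equal(perf$Sen, 1)
  expect_equal(perf$Sp, 1)
  # CSV column order
  tmp <- tempfile(fileext = ".csv")
  write_metrics_csv(rep, tmp)
  expect_identical(names(read.csv(tmp, check.names = FALSE))[1:9],
                   c("Loss", "Acc", "DC", "Sen", "Sp", "F1", "Pc", "M-IOU", "AUC"))
})
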