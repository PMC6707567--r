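# Dice coefficient/loss and the nine-score evaluation battery.

check_same_shape <- function(x, y) {
  if (!identical(dim(x) %||% length(x), dim(y) %||% length(y)))
    stop("mask shapes differ: ", paste(dim(x), collapse = "x"), " vs ",
         paste(dim(y), collapse = "x"), call. = FALSE)
}

check_binary <- function(x, what = "mask") {
  if (!all(x %in% c(0, 1)))
    stop(what, " must be strictly binary (0/1)", call. = FALSE)
  invisible(x)
}

#' Dice coefficient between two masks
#'
#' `DC = (2 |X ∩ Y| + s) / (|X| + |Y| + s)` with smoothing constant `s`
#' (default 1) so the empty-vs-empty case is defined (and equals 1). Accepts
#' soft probability maps for `y` (soft Dice, used as the training loss).
#'
#' @param x gold-standard mask (0/1).
#' @param y predicted mask (0/1) or probability map in `[0, 1]`.
#' @param smooth smoothing constant added to numerator and denominator.
#' @return Dice score in `[0, 1]`.
#' @export
dice_coefficient <- function(x, y, smooth = 1) {
  check_same_shape(x, y)
  (2 * sum(x * y) + smooth) / (sum(x) + sum(y) + smooth)
}

#' Dice loss
#'
#' `1 - dice_coefficient(x, y)`; with a soft `y` this is the training
#' objective.
#'
#' @inheritParams dice_coefficient
#' @return loss in `[0, 1]`.
#' @export
dice_loss <- function(x, y, smooth = 1) 1 - dice_coefficient(x, y, smooth)

# Gradient of the mean per-sample soft Dice loss w.r.t. the probability
# maps. gold, prob: (H, W, 1, N).
dice_loss_grad <- function(gold, prob, smooth = 1) {
  d <- dim(prob)
  n <- d[4]
  dy <- array(0, dim = d)
  for (i in seq_len(n)) {
    g <- gold[, , , i]
    p <- prob[, , , i]
    denom <- sum(g) + sum(p) + smooth
    num <- 2 * sum(g * p) + smooth
    dy[, , 1, i] <- -(2 * g * denom - num) / denom^2 / n
  }
  dy
}

#' Pixel confusion counts between gold and predicted masks
#'
#' Lesion pixels are the positive class.
#'
#' @param x gold-standard binary mask.
#' @param y predicted binary mask, same shape.
#' @return list with integer counts `tp`, `fp`, `fn`, `tn` (summing to the
#'   pixel total).
#' @export
confusion <- function(x, y) {
  check_same_shape(x, y)
  check_binary(x, "gold mask")
  check_binary(y, "predicted mask")
  tp <- sum(x == 1 & y == 1)
  fp <- sum(x == 0 & y == 1)
  fn <- sum(x == 1 & y == 0)
  tn <- sum(x == 0 & y == 0)
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Confusion-matrix scalar metrics
#'
#' Accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`, recall/sensitivity
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)` and F1 (harmonic mean of
#' precision and sensitivity). A zero denominator yields 0 by convention.
#'
#' @param counts list with `tp`, `fp`, `fn`, `tn`.
#' @return list `acc`, `pc`, `sen`, `sp`, `f1`, all in `[0, 1]`.
#' @export
scalar_metrics <- function(counts) {
  safe_div <- function(a, b) if (b > 0) a / b else 0
  with(counts, {
    acc <- safe_div(tp + tn, tp + fp + fn + tn)
    pc <- safe_div(tp, tp + fp)
    sen <- safe_div(tp, tp + fn)
    sp <- safe_div(tn, tn + fp)
    f1 <- if (pc + sen > 0) 2 * pc * sen / (pc + sen) else 0
    list(acc = acc, pc = pc, sen = sen, sp = sp, f1 = f1)
  })
}

iou <- function(x, y) {
  inter <- sum(x * y)
  uni <- sum(x) + sum(y) - inter
  if (uni > 0) inter / uni else 1
}

#' Mean intersection-over-union over mask pairs
#'
#' The lesion-class IOU `|X ∩ Y| / |X ∪ Y|` averaged over samples (the
#' index of the mean runs over images).
#'
#' @param gold list of gold binary masks (or a single mask).
#' @param pred list of predicted binary masks, same lengths/shapes.
#' @return mean IOU in `[0, 1]`.
#' @export
mean_iou <- function(gold, pred) {
  if (!is.list(gold)) gold <- list(gold)
  if (!is.list(pred)) pred <- list(pred)
  if (length(gold) == 0) stop("mean_iou: empty mask list", call. = FALSE)
  if (length(gold) != length(pred))
    stop("mean_iou: list lengths differ", call. = FALSE)
  mean(mapply(function(x, y) {
    check_same_shape(x, y)
    iou(x, y)
  }, gold, pred))
}

#' Pixel-pooled ROC and precision-recall AUC
#'
#' Pools all pixels of all images, sweeps every distinct probability as a
#' threshold, and integrates the ROC (and PR) curve by the trapezoid rule.
#'
#' @param gold list of binary masks (or one mask).
#' @param prob list of probability maps in `[0, 1]`, matching shapes.
#' @return list `roc_auc`, `pr_auc`, plus data.frame `roc` (fpr, tpr) and
#'   `pr` (recall, precision) curve points.
#' @export
auc_curves <- function(gold, prob) {
  if (!is.list(gold)) gold <- list(gold)
  if (!is.list(prob)) prob <- list(prob)
  g <- unlist(lapply(gold, as.numeric))
  p <- unlist(lapply(prob, as.numeric))
  if (length(g) != length(p))
    stop("auc_curves: pooled lengths differ", call. = FALSE)
  npos <- sum(g == 1)
  nneg <- sum(g == 0)
  if (npos == 0 || nneg == 0)
    stop("AUC undefined: pooled gold standard contains a single class",
         call. = FALSE)
  ord <- order(p, decreasing = TRUE)
  gs <- g[ord]
  ps <- p[ord]
  tp <- cumsum(gs)
  fp <- cumsum(1 - gs)
  keep <- c(ps[-1] != ps[-length(ps)], TRUE)  # last index of each threshold
  tp <- tp[keep]; fp <- fp[keep]
  tpr <- c(0, tp / npos)
  fpr <- c(0, fp / nneg)
  prec <- c(1, tp / (tp + fp))
  roc_auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  pr_auc <- sum(diff(tpr) * (prec[-1] + prec[-length(prec)]) / 2)
  list(roc_auc = roc_auc, pr_auc = pr_auc,
       roc = data.frame(fpr = fpr, tpr = tpr),
       pr = data.frame(recall = tpr, precision = prec))
}

#' Nine-score evaluation report for a set of predictions
#'
#' Computes the full battery for a test set: soft Dice loss and Dice
#' coefficient averaged per image, pooled confusion-matrix scores
#' (accuracy, sensitivity, specificity, F1, precision), mean lesion IOU,
#' and pixel-pooled ROC/PR AUC. Probability maps are binarised at
#' `threshold` before confusion counting.
#'
#' @param gold list of gold binary masks.
#' @param prob list of predicted probability maps, matching shapes.
#' @param threshold binarisation threshold, default 0.5.
#' @return object of class `metrics_report`: a one-row data.frame with
#'   columns Loss, Acc, DC, Sen, Sp, F1, Pc, M-IOU, AUC (plus AUC_PR);
#'   attributes `per_image` (data.frame) and `curves`.
#' @export
metrics_report <- function(gold, prob, threshold = 0.5) {
  if (!is.list(gold)) gold <- list(gold)
  if (!is.list(prob)) prob <- list(prob)
  stopifnot(length(gold) == length(prob), length(gold) > 0)
  bin <- lapply(prob, function(p) (p > threshold) * 1)
  per <- data.frame(
    image = seq_along(gold),
    loss = mapply(dice_loss, gold, prob),
    dc = mapply(function(x, y) dice_coefficient(x, y), gold, bin),
    iou = mapply(iou, gold, bin))
  counts <- Reduce(function(a, b) Map(`+`, a, b), Map(confusion, gold, bin))
  sm <- scalar_metrics(counts)
  curves <- tryCatch(auc_curves(gold, prob), error = function(e) NULL)
  row <- data.frame(
    Loss = mean(per$loss), Acc = sm$acc, DC = mean(per$dc), Sen = sm$sen,
    Sp = sm$sp, F1 = sm$f1, Pc = sm$pc, `M-IOU` = mean(per$iou),
    AUC = if (is.null(curves)) NA_real_ else curves$roc_auc,
    AUC_PR = if (is.null(curves)) NA_real_ else curves$pr_auc,
    check.names = FALSE)
  structure(row, class = c("metrics_report", "data.frame"),
            per_image = per, curves = curves, confusion = counts)
}

#' Write a metrics report as CSV in the canonical column order
#'
#' Column order Loss, Acc, DC, Sen, Sp, F1, Pc, M-IOU, AUC (AUC_PR
#' appended last).
#'
#' @param report a [metrics_report()] (or a data.frame of such rows).
#' @param path output CSV path.
#' @export
write_metrics_csv <- function(report, path) {
  cols <- c("Loss", "Acc", "DC", "Sen", "Sp", "F1", "Pc", "M-IOU", "AUC")
  extra <- setdiff(names(report), cols)
  df <- as.data.frame(report)[, c(intersect(names(report), cols), extra),
                              drop = FALSE]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
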