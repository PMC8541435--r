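# Segmentation evaluation: confusion counts with foreground = positive class,
# precision/recall/F1, Dice, Jaccard, and macro (per-image mean) vs micro
# (pooled counts) aggregation.

#' Pixelwise confusion counts between a prediction and ground truth
#'
#' @param pred,gt 0/1 matrices of identical shape (1 = IMC foreground).
#' @return a `confusion_counts` object with fields TP, FP, FN, TN.
#' @export
confusion <- function(pred, gt) {
  assert_mask(pred, "pred"); assert_mask(gt, "gt")
  if (!identical(dim(pred), dim(gt))) stop_cfg("pred and gt shapes differ")
  p <- pred == 1; g <- gt == 1
  structure(list(TP = sum(p & g), FP = sum(p & !g),
                 FN = sum(!p & g), TN = sum(!p & !g)),
            class = "confusion_counts")
}

counts <- function(TP, FP, FN, TN = 0) {
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN), class = "confusion_counts")
}

ratio0 <- function(num, den) if (den == 0) 0 else num / den

#' Precision, recall and F1 from confusion counts
#'
#' Degenerate 0/0 ratios are defined as 0 (and only arise when there is no
#' predicted or no true foreground). F1 is evaluated as `2TP / (2TP+FP+FN)`,
#' the count-level form of `2PR / (P+R)` — identical in real arithmetic, but
#' exact in floating point, so the micro-F1 = micro-Dice identity holds
#' bit-for-bit.
#'
#' @param c a `confusion_counts` object.
#' @return named numeric vector `(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(c) {
  p <- ratio0(c$TP, c$TP + c$FP)
  r <- ratio0(c$TP, c$TP + c$FN)
  f1 <- ratio0(2 * c$TP, 2 * c$TP + c$FP + c$FN)
  c(precision = p, recall = r, f1 = f1)
}

#' Dice coefficient `2TP / (2TP + FP + FN)`
#'
#' Empty-vs-empty (no foreground on either side) is 1 by convention.
#'
#' @param c a `confusion_counts` object.
#' @return Dice in \[0,1\].
#' @export
dice <- function(c) {
  if (c$TP + c$FP + c$FN == 0) return(1)
  2 * c$TP / (2 * c$TP + c$FP + c$FN)
}

#' Jaccard index `TP / (TP + FP + FN)` (intersection over union)
#'
#' @param c a `confusion_counts` object.
#' @return Jaccard in \[0,1\]; empty-vs-empty is 1.
#' @export
jaccard <- function(c) {
  if (c$TP + c$FP + c$FN == 0) return(1)
  c$TP / (c$TP + c$FP + c$FN)
}

metric_row <- function(c) {
  prf <- precision_recall_f1(c)
  c(prf, dice = dice(c), jaccard = jaccard(c))
}

#' Evaluate a set of predictions against ground-truth masks
#'
#' Macro averaging is the mean of per-image metrics; micro averaging computes
#' the metrics once on counts pooled over all images. Micro F1 and micro Dice
#' coincide algebraically; macro values generally differ.
#'
#' @param preds,gts equal-length lists of shape-matched 0/1 matrices.
#' @param averaging `"macro"` (default headline) or `"micro"`.
#' @return a `metric_report`: precision, recall, f1, dice, jaccard, the
#'   averaging mode, and a per-image table.
#' @export
evaluate_set <- function(preds, gts, averaging = c("macro", "micro")) {
  averaging <- match.arg(averaging)
  if (length(preds) != length(gts)) stop_cfg("preds and gts lengths differ")
  if (length(preds) == 0) stop_cfg("empty evaluation set")
  per <- t(vapply(seq_along(preds),
                  function(i) metric_row(confusion(preds[[i]], gts[[i]])),
                  numeric(5)))
  per <- as.data.frame(per)
  if (averaging == "macro") {
    agg <- colMeans(per)
  } else {
    cs <- lapply(seq_along(preds), function(i) confusion(preds[[i]], gts[[i]]))
    pooled <- counts(sum(vapply(cs, `[[`, numeric(1), "TP")),
                     sum(vapply(cs, `[[`, numeric(1), "FP")),
                     sum(vapply(cs, `[[`, numeric(1), "FN")),
                     sum(vapply(cs, `[[`, numeric(1), "TN")))
    agg <- metric_row(pooled)
  }
  structure(list(precision = agg[["precision"]], recall = agg[["recall"]],
                 f1 = agg[["f1"]], dice = agg[["dice"]],
                 jaccard = agg[["jaccard"]], averaging = averaging,
                 per_image = per),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("%s-averaged over %d images:\n", x$averaging, nrow(x$per_image)))
  cat(sprintf("  precision %.4f  recall %.4f  F1 %.4f  Dice %.4f  Jaccard %.4f\n",
              x$precision, x$recall, x$f1, x$dice, x$jaccard))
  invisible(x)
}
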