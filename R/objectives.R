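# Training objective (combined BCE + Dice) and the evaluation metric suite.
# Predicted probability maps are binarized at 0.4 (chosen in the source
# study via ROC analysis) with a strict ">" so the threshold behaves like an
# ROC operating point.

#' Binarize a probability map
#'
#' @param prob_map numeric array/matrix of probabilities in `[0, 1]`.
#' @param threshold scalar in (0, 1); a pixel becomes 1 iff its probability
#'   strictly exceeds it. Default 0.4.
#' @return an integer-valued object of the same shape with values in
#'   `{0, 1}`.
#' @export
binarize <- function(prob_map, threshold = 0.4) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must be a single value in (0, 1)")
  out <- (prob_map > threshold) + 0L
  if (!is.null(dim(prob_map))) dim(out) <- dim(prob_map)
  out
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(p*g) + smooth) / (sum(p) + sum(g) + smooth)`, the
#' differentiable relaxation of `1 - Dice` used as half of the training
#' objective. The smoothing constant guards the 0/0 case of empty masks
#' (common here: "no mass" frames have all-zero ground truth).
#'
#' @param prob_map predicted probabilities.
#' @param gt_mask binary ground-truth mask, same shape.
#' @param smooth smoothing constant (default 1e-6).
#' @return scalar loss in `[0, 1]`.
#' @export
soft_dice_loss <- function(prob_map, gt_mask, smooth = 1e-6) {
  stopifnot(length(prob_map) == length(gt_mask))
  1 - (2 * sum(prob_map * gt_mask) + smooth) /
    (sum(prob_map) + sum(gt_mask) + smooth)
}

.bce_loss <- function(prob_map, gt_mask, eps = 1e-7) {
  p <- pmin(pmax(prob_map, eps), 1 - eps)
  -mean(gt_mask * log(p) + (1 - gt_mask) * log(1 - p))
}

#' Combined BCE + Dice loss
#'
#' The training objective: mean pixelwise binary cross-entropy plus the soft
#' Dice loss, with unit weights by default.
#'
#' @inheritParams soft_dice_loss
#' @param bce_weight,dice_weight term weights (default 1 each).
#' @return scalar loss (non-negative).
#' @export
combined_loss <- function(prob_map, gt_mask, bce_weight = 1, dice_weight = 1,
                          smooth = 1e-6) {
  bce_weight * .bce_loss(prob_map, gt_mask) +
    dice_weight * soft_dice_loss(prob_map, gt_mask, smooth)
}

# gradient of the combined loss wrt the probability map (used in training)
.combined_loss_grad <- function(prob_map, gt_mask, bce_weight = 1,
                                dice_weight = 1, smooth = 1e-6,
                                eps = 1e-7) {
  p <- pmin(pmax(prob_map, eps), 1 - eps)
  dbce <- (p - gt_mask) / (p * (1 - p)) / length(p)
  num <- 2 * sum(prob_map * gt_mask) + smooth
  den <- sum(prob_map) + sum(gt_mask) + smooth
  ddice <- (num - 2 * gt_mask * den) / den^2
  g <- bce_weight * dbce + dice_weight * ddice
  dim(g) <- dim(prob_map)
  g
}

#' Pixel confusion counts
#'
#' @param pred binary predicted mask.
#' @param gt binary ground-truth mask, same shape.
#' @return list with `tp`, `fp`, `tn`, `fn` pixel counts (summing to the
#'   total number of pixels).
#' @export
confusion_counts <- function(pred, gt) {
  if (length(pred) != length(gt)) stop("pred and gt differ in size")
  p <- as.logical(pred); g <- as.logical(gt)
  list(tp = sum(p & g), fp = sum(p & !g), tn = sum(!p & !g), fn = sum(!p & g))
}

#' Metrics from confusion counts
#'
#' Standard confusion-matrix definitions; ratios with a zero denominator are
#' returned as `NA` (undefined), never silently as 0. On binary masks the
#' Dice coefficient `2tp / (2tp + fp + fn)` equals the F1 score.
#'
#' @param counts a list with `tp`, `fp`, `tn`, `fn`.
#' @return a one-row `data.frame` with columns `accuracy`, `precision`,
#'   `sensitivity`, `specificity`, `f1`, `dice_coefficient`.
#' @export
metrics_from_counts <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  sdiv <- function(a, b) if (b > 0) a / b else NA_real_
  precision <- sdiv(tp, tp + fp)
  sensitivity <- sdiv(tp, tp + fn)
  f1 <- if (!is.na(precision) && !is.na(sensitivity) &&
            (precision + sensitivity) > 0)
    2 * precision * sensitivity / (precision + sensitivity)
  else sdiv(2 * tp, 2 * tp + fp + fn)
  data.frame(
    accuracy = sdiv(tp + tn, tp + fp + tn + fn),
    precision = precision,
    sensitivity = sensitivity,
    specificity = sdiv(tn, tn + fp),
    f1 = f1,
    dice_coefficient = sdiv(2 * tp, 2 * tp + fp + fn))
}

#' Segmentation metrics of a probability map against a ground-truth mask
#'
#' Binarizes the prediction (strict `>` at `threshold`) and reports the
#' confusion-matrix metric suite together with the combined loss and the
#' soft Dice loss of the un-binarized probabilities.
#'
#' @inheritParams soft_dice_loss
#' @param threshold binarization threshold (default 0.4).
#' @return a one-row `data.frame`: `accuracy`, `precision`, `sensitivity`,
#'   `specificity`, `f1`, `dice_coefficient`, `loss`, `dice_loss`.
#' @export
compute_metrics <- function(prob_map, gt_mask, threshold = 0.4) {
  m <- metrics_from_counts(confusion_counts(binarize(prob_map, threshold),
                                            gt_mask))
  m$loss <- combined_loss(prob_map, gt_mask)
  m$dice_loss <- soft_dice_loss(prob_map, gt_mask)
  m
}

#' Dice coefficient of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; symmetric in its arguments; 1 when both masks
#' are empty (perfect agreement).
#'
#' @param a,b binary masks of equal shape.
#' @return scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(length(a) == length(b))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a * b) / (sa + sb)
}
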