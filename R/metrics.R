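#' Pixel confusion counts
#'
#' Tallies the four-way pixel classification between a predicted and a
#' ground-truth binary mask: TP (polyp pixels found), FP (background called
#' polyp), TN (background kept), FN (polyp pixels missed).
#'
#' @param pred_mask,gt_mask Binary (0/1) arrays of equal shape.
#' @return Object of class `confusion_counts`: list with `tp`, `fp`, `tn`,
#'   `fn`; the four always sum to the pixel count.
#' @export
confusion <- function(pred_mask, gt_mask) {
  check_loss_shapes(pred_mask, gt_mask)
  if (!all(pred_mask %in% c(0, 1)) || !all(gt_mask %in% c(0, 1))) {
    stop("masks must be strictly binary (0/1)", call. = FALSE)
  }
  p <- pred_mask == 1
  g <- gt_mask == 1
  structure(list(
    tp = sum(p & g), fp = sum(p & !g),
    tn = sum(!p & !g), fn = sum(!p & g)
  ), class = "confusion_counts")
}

#' Count-based segmentation measures
#'
#' Per-image measures from [confusion()] counts, with the usual degenerate
#' conventions: when a denominator is zero (e.g. both masks empty for Dice,
#' empty ground truth for sensitivity) the measure is 1 — the prediction
#' cannot be faulted on pixels that do not exist.
#'
#' * `dice_coefficient`: `2 TP / (2 TP + FP + FN)`
#' * `iou`: `TP / (TP + FP + FN)` (Jaccard index)
#' * `sensitivity`: `TP / (TP + FN)` (polyp recall)
#' * `specificity`: `TN / (TN + FP)` (background recall)
#'
#' @param counts A `confusion_counts` object.
#' @return Fraction in `[0, 1]`.
#' @export
dice_coefficient <- function(counts) {
  den <- 2 * counts$tp + counts$fp + counts$fn
  if (den == 0) return(1)
  2 * counts$tp / den
}

#' @rdname dice_coefficient
#' @export
iou <- function(counts) {
  den <- counts$tp + counts$fp + counts$fn
  if (den == 0) return(1)
  counts$tp / den
}

#' @rdname dice_coefficient
#' @export
sensitivity <- function(counts) {
  den <- counts$tp + counts$fn
  if (den == 0) return(1)
  counts$tp / den
}

#' @rdname dice_coefficient
#' @export
specificity <- function(counts) {
  den <- counts$tn + counts$fp
  if (den == 0) return(1)
  counts$tn / den
}

#' Structure measure (S-measure)
#'
#' Structural similarity between a probability map and a binary ground
#' truth: `alpha * S_O + (1 - alpha) * S_R` with `alpha = 0.5` canonically.
#' `S_O` is the object-aware component (foreground/background mean and
#' dispersion of the prediction compared against the ground-truth regions);
#' `S_R` is the region-aware component (the ground-truth centroid splits
#' both maps into four quadrants, each compared with an SSIM-style
#' statistic, combined with area weights).  Degenerate ground truths follow
#' the reference conventions: all-background scores `1 - mean(pred)`,
#' all-foreground scores `mean(pred)`.
#'
#' @param pred Numeric matrix of probabilities in `[0, 1]`.
#' @param gt Binary matrix of the same shape.
#' @param alpha Object/region mixing weight in `[0, 1]`.
#' @return Score in `[0, 1]`.
#' @export
s_measure <- function(pred, gt, alpha = 0.5) {
  check_loss_shapes(pred, gt)
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]", call. = FALSE)
  pred <- as.matrix(pred)
  gt <- as.matrix(gt)
  y <- mean(gt)
  if (y == 0) return(clamp01(1 - mean(pred)))
  if (y == 1) return(clamp01(mean(pred)))
  q <- alpha * sm_object(pred, gt) + (1 - alpha) * sm_region(pred, gt)
  clamp01(q)
}

clamp01 <- function(x) min(max(x, 0), 1)

sm_object <- function(pred, gt) {
  fg <- gt == 1
  obj <- function(vals) {
    x <- mean(vals)
    sx <- stats::sd(vals)
    if (is.na(sx)) sx <- 0
    2 * x / (x^2 + 1 + sx + .Machine$double.eps)
  }
  o_fg <- obj(pred[fg])
  o_bg <- obj((1 - pred)[!fg])
  u <- mean(gt)
  u * o_fg + (1 - u) * o_bg
}

sm_region <- function(pred, gt) {
  nr <- nrow(gt)
  nc <- ncol(gt)
  a <- sum(gt)
  if (a == 0) {
    ci <- round(nr / 2)
    cj <- round(nc / 2)
  } else {
    ij <- which(gt == 1, arr.ind = TRUE)
    ci <- round(mean(ij[, 1]))
    cj <- round(mean(ij[, 2]))
  }
  ci <- min(max(ci, 1L), nr)
  cj <- min(max(cj, 1L), nc)
  rows <- list(1:ci, if (ci < nr) (ci + 1L):nr else integer(0))
  cols <- list(1:cj, if (cj < nc) (cj + 1L):nc else integer(0))
  total <- nr * nc
  q <- 0
  for (r in 1:2) {
    for (c in 1:2) {
      if (!length(rows[[r]]) || !length(cols[[c]])) next
      gq <- gt[rows[[r]], cols[[c]], drop = FALSE]
      pq <- pred[rows[[r]], cols[[c]], drop = FALSE]
      w <- length(gq) / total
      q <- q + w * sm_ssim(pq, gq)
    }
  }
  q
}

# SSIM-style regional statistic on means, dispersions and covariance.
sm_ssim <- function(pred, gt) {
  n <- length(gt)
  x <- mean(pred)
  y <- mean(gt)
  if (n == 1) {
    sx2 <- sy2 <- sxy <- 0
  } else {
    sx2 <- sum((pred - x)^2) / (n - 1)
    sy2 <- sum((gt - y)^2) / (n - 1)
    sxy <- sum((pred - x) * (gt - y)) / (n - 1)
  }
  aa <- 4 * x * y * sxy
  bb <- (x^2 + y^2) * (sx2 + sy2)
  if (aa != 0) {
    aa / (bb + .Machine$double.eps)
  } else if (bb == 0) {
    1
  } else {
    0
  }
}

#' Mean absolute error
#'
#' Per-pixel mean absolute difference between the probability map and the
#' binary ground truth.
#'
#' @param pred Numeric array of probabilities.
#' @param gt Binary array of the same shape.
#' @return Fraction in `[0, 1]`.
#' @export
mae <- function(pred, gt) {
  check_loss_shapes(pred, gt)
  mean(abs(gt - pred))
}

#' Evaluate a set of predictions
#'
#' Computes the six segmentation measures averaged over images: mDice, mIoU,
#' sensitivity and specificity on masks binarized at `threshold`, and
#' S-measure and MAE on the raw probability maps.
#'
#' @param pairs Non-empty list; each element a list with `pred` (probability
#'   matrix) and `gt` (binary matrix of equal shape).
#' @param threshold Binarization threshold for the count-based measures.
#' @param sm_alpha S-measure mixing weight.
#' @return A one-row tibble: `mdice`, `miou`, `sens`, `spe`, `sm`, `mae`,
#'   `n_images`.
#' @export
evaluate_set <- function(pairs, threshold = 0.5, sm_alpha = 0.5) {
  if (!length(pairs)) stop("pairs must be non-empty", call. = FALSE)
  per <- vapply(pairs, function(p) {
    cm <- confusion(predict_mask(p$pred, threshold), p$gt)
    c(dice_coefficient(cm), iou(cm), sensitivity(cm), specificity(cm),
      s_measure(p$pred, p$gt, sm_alpha), mae(p$pred, p$gt))
  }, numeric(6))
  m <- rowMeans(per)
  tibble::tibble(
    mdice = m[1], miou = m[2], sens = m[3], spe = m[4],
    sm = m[5], mae = m[6], n_images = length(pairs)
  )
}
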