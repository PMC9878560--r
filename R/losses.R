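#' Loss configuration
#'
#' Settings for the compound Dice + focal objective.  The focal weighting
#' `alpha` balances foreground against background pixels and `gamma` is the
#' focusing exponent that down-weights easy pixels; the defaults (0.25, 2)
#' are the established focal-loss values.  `smooth` is the Dice smoothing
#' constant guarding empty masks.  The two components are combined as
#' `w_dice * Dice + w_focal * focal`; the default is the plain unweighted
#' sum.
#'
#' @param alpha Focal class-balance weight in `[0, 1]`.
#' @param gamma Focal focusing exponent `>= 0`.
#' @param smooth Nonnegative Dice smoothing constant.
#' @param w_dice,w_focal Component weights.
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(alpha = 0.25, gamma = 2, smooth = 1,
                        w_dice = 1, w_focal = 1) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]", call. = FALSE)
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  if (smooth < 0) stop("smooth must be >= 0", call. = FALSE)
  structure(list(alpha = alpha, gamma = gamma, smooth = smooth,
                 w_dice = w_dice, w_focal = w_focal),
            class = "loss_config")
}

.loss_eps <- 1e-7

check_loss_shapes <- function(pred, target) {
  if (!identical(dim(pred) %||% length(pred),
                 dim(target) %||% length(target))) {
    stop("pred and target must have identical shapes", call. = FALSE)
  }
}

#' Dice loss
#'
#' `1 - (2 * sum(pred * target) + smooth) / (sum(pred) + sum(target) +
#' smooth)`: one minus the soft Dice overlap between the predicted
#' probability map and the binary target.  Ranges over `[0, 1]`: 0 for a
#' perfect binary match, 1 for disjoint non-empty masks.  With `smooth = 0`
#' and both masks empty the loss is defined as 0 (perfect agreement).
#'
#' @param pred Numeric array of probabilities in `[0, 1]`.
#' @param target Binary array of the same shape.
#' @param smooth Nonnegative smoothing constant.
#' @return Scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(pred, target, smooth = 1) {
  check_loss_shapes(pred, target)
  inter <- sum(pred * target)
  denom <- sum(pred) + sum(target)
  if (denom + smooth == 0) return(0)
  1 - (2 * inter + smooth) / (denom + smooth)
}

#' Focal loss
#'
#' The two-sided focal loss: with `p_t = pred` on foreground pixels and
#' `1 - pred` on background pixels, and `alpha_t = alpha` / `1 - alpha`
#' correspondingly, each pixel contributes
#' `-alpha_t * (1 - p_t)^gamma * log(p_t)`; the result is the mean over
#' pixels.  Probabilities are clamped to `[1e-7, 1 - 1e-7]` before the log.
#' `alpha = 1` disables class weighting (both classes weighted 1), so that
#' `gamma = 0`, `alpha = 1` reduces exactly to mean binary cross-entropy.
#'
#' @param pred Numeric array of probabilities.
#' @param target Binary array of the same shape.
#' @param alpha Class-balance weight in `[0, 1]`.
#' @param gamma Focusing exponent `>= 0`.
#' @return Nonnegative scalar (mean over pixels).
#' @export
focal_loss <- function(pred, target, alpha = 0.25, gamma = 2) {
  check_loss_shapes(pred, target)
  p <- pmin(pmax(pred, .loss_eps), 1 - .loss_eps)
  fg <- target == 1
  pt <- ifelse(fg, p, 1 - p)
  at <- if (alpha == 1) 1 else ifelse(fg, alpha, 1 - alpha)
  mean(-at * (1 - pt)^gamma * log(pt))
}

#' Compound segmentation loss
#'
#' The training objective: the (weighted) sum of [dice_loss()] and
#' [focal_loss()], by default the plain sum.
#'
#' @param pred Numeric array of probabilities.
#' @param target Binary array of the same shape.
#' @param cfg A [loss_config()].
#' @return Scalar loss.
#' @export
total_loss <- function(pred, target, cfg = loss_config()) {
  cfg$w_dice * dice_loss(pred, target, cfg$smooth) +
    cfg$w_focal * focal_loss(pred, target, cfg$alpha, cfg$gamma)
}

# Tape op: compound loss over a batch node (H, W, 1, N) with analytic
# gradient.  Dice is computed per image then averaged; focal is the mean
# over all pixels of the batch (images share a size, so this equals the
# per-image mean of means).
tg_seg_loss <- function(pred, target, cfg = loss_config()) {
  d <- dim(pred$v)
  N <- d[4]
  npix <- d[1] * d[2] * d[3]
  eps <- .loss_eps
  lo <- pred$v < eps
  hi <- pred$v > 1 - eps
  p <- pmin(pmax(pred$v, eps), 1 - eps)
  t <- target
  pm <- matrix(p, npix, N)
  tm <- matrix(t, npix, N)
  inter <- colSums(pm * tm)
  denom <- colSums(pm) + colSums(tm)
  s <- cfg$smooth
  dice_i <- 1 - (2 * inter + s) / (denom + s)
  Ld <- mean(dice_i)
  fg <- tm == 1
  pt <- ifelse(fg, pm, 1 - pm)
  at <- if (cfg$alpha == 1) 1 else ifelse(fg, cfg$alpha, 1 - cfg$alpha)
  om <- 1 - pt
  Lf <- mean(-at * om^cfg$gamma * log(pt))
  value <- cfg$w_dice * Ld + cfg$w_focal * Lf
  tg_node(value, parents = pred$id, backfn = function(g) {
    # Dice: d/dp_i [1 - (2I+s)/(S+s)] = -(2 t (S+s) - (2I+s)) / (S+s)^2
    dd <- -(2 * tm * matrix(denom + s, npix, N, byrow = TRUE) -
              matrix(2 * inter + s, npix, N, byrow = TRUE)) /
      matrix((denom + s)^2, npix, N, byrow = TRUE)
    dd <- dd / N
    # focal: d/dp of -at (1-pt)^g log(pt), with pt = p (fg) or 1-p (bg)
    gam <- cfg$gamma
    dpt <- if (gam == 0) {
      -at / pt
    } else {
      at * (gam * om^(gam - 1) * log(pt) - om^gam / pt)
    }
    df <- ifelse(fg, dpt, -dpt) / (npix * N)
    dL <- cfg$w_dice * dd + cfg$w_focal * df
    dL[lo | hi] <- 0 # clamped pixels pass no gradient
    dim(dL) <- d
    list(g * dL)
  })
}
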