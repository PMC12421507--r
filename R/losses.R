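# Loss functions of the two network branches and the aggregated training
# channel.

#' Multi-class soft Dice loss
#'
#' `1 - mean over classes of (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)`
#' where `p` is the predicted per-pixel class probability and `t` the one-hot
#' target. Used in the categorical (border) branch because it is insensitive
#' to the large size imbalance between cell bodies and EV puncta.
#'
#' @param pred numeric array `H x W x C` of per-pixel class probabilities
#'   (each pixel sums to 1).
#' @param target integer matrix of class indices in `0..C-1`.
#' @param eps smoothing constant.
#' @return Scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(pred, target, eps = 1e-6) {
  stopifnot(length(dim(pred)) == 3L, is.matrix(target))
  if (!identical(dim(pred)[1:2], dim(target))) {
    stop("dice_loss: prediction and target shapes differ")
  }
  C <- dim(pred)[3]
  stopifnot(all(target >= 0), all(target <= C - 1))
  per_class <- vapply(seq_len(C), function(c) {
    p <- pred[, , c]
    t <- (target == c - 1) + 0
    (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)
  }, numeric(1))
  1 - mean(per_class)
}

# Gradient of dice_loss with respect to pred (same shape as pred).
dice_loss_grad <- function(pred, target, eps = 1e-6) {
  C <- dim(pred)[3]
  g <- array(0, dim = dim(pred))
  for (c in seq_len(C)) {
    p <- pred[, , c]
    t <- (target == c - 1) + 0
    num <- 2 * sum(p * t) + eps
    den <- sum(p) + sum(t) + eps
    g[, , c] <- -(2 * t * den - num) / den^2 / C
  }
  g
}

#' Smooth L1 (Huber-like) loss
#'
#' Mean over pixels of `0.5 * d^2 / beta` when `|d| < beta`, else
#' `|d| - 0.5 * beta`, with `d = pred - target`. Used in the regression
#' (distance) branch: quadratic near zero for stable gradients, linear in
#' the tails so single badly-predicted pixels cannot dominate.
#'
#' @param pred,target numeric matrices of identical shape.
#' @param beta transition point (> 0).
#' @return Scalar loss (>= 0).
#' @export
smooth_l1 <- function(pred, target, beta = 1) {
  stopifnot(beta > 0)
  if (!identical(dim(pred), dim(target))) {
    stop("smooth_l1: prediction and target shapes differ")
  }
  d <- abs(pred - target)
  mean(ifelse(d < beta, 0.5 * d^2 / beta, d - 0.5 * beta))
}

# Gradient of smooth_l1 with respect to pred.
smooth_l1_grad <- function(pred, target, beta = 1) {
  d <- pred - target
  g <- ifelse(abs(d) < beta, d / beta, sign(d))
  g / length(d)
}

# Optional weighted cross-entropy addition for the categorical branch
# (config switch `cls_loss = "dice_ce"`); class weights are inverse pixel
# frequencies of the target.
weighted_ce <- function(pred, target, eps = 1e-8) {
  C <- dim(pred)[3]
  counts <- vapply(seq_len(C), function(c) sum(target == c - 1), numeric(1))
  wts <- ifelse(counts > 0, 1 / counts, 0)
  wts <- wts / sum(wts)
  loss <- 0
  for (c in seq_len(C)) {
    sel <- target == c - 1
    if (any(sel)) {
      loss <- loss - wts[c] * mean(log(pred[, , c][sel] + eps))
    }
  }
  loss
}

weighted_ce_grad <- function(pred, target, eps = 1e-8) {
  C <- dim(pred)[3]
  counts <- vapply(seq_len(C), function(c) sum(target == c - 1), numeric(1))
  wts <- ifelse(counts > 0, 1 / counts, 0)
  wts <- wts / sum(wts)
  g <- array(0, dim = dim(pred))
  for (c in seq_len(C)) {
    sel <- target == c - 1
    if (any(sel)) {
      gc <- matrix(0, nrow(target), ncol(target))
      gc[sel] <- -wts[c] / (pred[, , c][sel] + eps) / sum(sel)
      g[, , c] <- gc
    }
  }
  g
}

#' Aggregate the three channels into one training image
#'
#' Each plane is min-max normalized to `[0, 1]` (a constant plane contributes
#' zero) and the per-pixel maximum is taken, producing a single channel in
#' which cells, nuclei and EVs are all visible. One network is trained on
#' this aggregated channel and then applied to each plane separately at
#' inference.
#'
#' @param frame a [multichannel_frame()].
#' @return Numeric matrix in `[0, 1]`.
#' @export
aggregate_channel <- function(frame) {
  stopifnot(inherits(frame, "multichannel_frame"))
  pmax(
    minmax_norm(frame$nuclei_plane),
    minmax_norm(frame$ev_plane),
    minmax_norm(frame$merge_plane)
  )
}
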