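#' Weighted categorical cross-entropy
#'
#' The multi-class segmentation loss: per voxel,
#' `-sum_i t_i * log(p_i) * w_i` with the index running over the `N`
#' classes, averaged over voxels. Predicted probabilities are clipped to
#' `[epsilon, 1 - epsilon]` before the logarithm. With all weights equal to
#' one this reduces to the unweighted categorical cross-entropy. The default
#' class weights (background plus four cut classes) compensate for the
#' extreme foreground/background imbalance of thin cut regions.
#'
#' @param target n_voxels x n_classes matrix (or length-`n_classes` vector
#'   for a single voxel) of one-hot targets.
#' @param pred Matching matrix/vector of predicted class probabilities
#'   (rows sum to 1).
#' @param weights Per-class weights; default `c(10, 270, 260, 270, 260)`
#'   for 5 classes, otherwise all ones.
#' @param epsilon Clipping constant.
#' @return Non-negative scalar loss (mean over voxels).
#' @examples
#' wcce_loss(c(1, 0), c(0.5, 0.5), weights = c(1, 1))  # -log(0.5)
#' @export
wcce_loss <- function(target, pred, weights = NULL, epsilon = 1e-7) {
  if (is.null(dim(target))) target <- matrix(target, nrow = 1)
  if (is.null(dim(pred))) pred <- matrix(pred, nrow = 1)
  if (!all(dim(target) == dim(pred)))
    stop("target and pred must have identical shapes")
  nc <- ncol(target)
  if (is.null(weights)) weights <- if (nc == 5) c(10, 270, 260, 270, 260) else rep(1, nc)
  if (length(weights) != nc) stop("need one weight per class")
  p <- pmin(pmax(pred, epsilon), 1 - epsilon)
  per_vox <- -(target * log(p)) %*% weights
  mean(per_vox)
}

#' Dice cross-entropy compound loss
#'
#' The binary segmentation loss used for the pelvis-mask network:
#' `(1 - alpha) * L_CE + alpha * L_Dice` with `alpha = 0.5`, where `L_CE`
#' is the mean binary cross-entropy and `L_Dice = 1 - soft Dice`
#' (`2 * sum(p*t) / (sum(p) + sum(t))`).
#'
#' @param pred Predicted foreground probabilities in `[0, 1]` (any shape).
#' @param target Binary mask of the same shape.
#' @param alpha Mixing weight in `[0, 1]`; 0 gives plain cross-entropy,
#'   1 the pure Dice term.
#' @param epsilon Clipping constant for the logarithms and an additive
#'   smoothing term in the Dice denominator.
#' @return Non-negative scalar loss.
#' @export
dice_ce_loss <- function(pred, target, alpha = 0.5, epsilon = 1e-7) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  pred <- as.numeric(pred)
  target <- as.numeric(target)
  if (length(pred) != length(target))
    stop("pred and target must have identical shapes")
  if (any(target != 0 & target != 1)) stop("target must be binary")
  p <- pmin(pmax(pred, epsilon), 1 - epsilon)
  ce <- -mean(target * log(p) + (1 - target) * log(1 - p))
  dice <- 2 * sum(pred * target) / (sum(pred) + sum(target) + epsilon)
  (1 - alpha) * ce + alpha * (1 - dice)
}
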