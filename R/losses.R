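# Loss family: soft Dice loss (sum-denominator training variant and
# squared-denominator variant), the documented Dice gradient expression,
# summed binary cross-entropy with its logit-space gradient, and the mean
# negative log-likelihood for the 2-way classifier head.

#' Soft Dice loss
#'
#' `1 - (2 * sum(P*T) + s) / (sum(P) + sum(T) + s)` for the `"sum"` variant
#' (the training default); the `"squared"` variant uses `sum(P^2) + sum(T^2)`
#' in the denominator. The smoothing constant `s` stabilizes the loss when
#' both masks are nearly empty; with `smooth = 0` and two empty masks the
#' loss is undefined and rejected.
#'
#' @param P probability volume (array in `[0, 1]`).
#' @param T_ binary ground-truth mask (array).
#' @param variant `"sum"` or `"squared"` denominator.
#' @param smooth smoothing constant added to numerator and denominator.
#' @return scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(P, T_, variant = c("sum", "squared"), smooth = 1e-5) {
  variant <- match.arg(variant)
  if (!identical(dim(P), dim(T_)) && length(P) != length(T_)) {
    stop("P and T must have the same shape")
  }
  P <- as.numeric(P); T_ <- as.numeric(T_)
  num <- 2 * sum(P * T_) + smooth
  den <- smooth + if (variant == "sum") sum(P) + sum(T_) else
    sum(P * P) + sum(T_ * T_)
  if (den == 0) stop("Dice loss undefined: both masks empty and smoothing disabled")
  1 - num / den
}

# Gradient of the sum-variant soft Dice loss w.r.t. P (used for training).
dice_loss_grad <- function(P, T_, smooth = 1e-5) {
  P <- as.numeric(P); T_ <- as.numeric(T_)
  num <- 2 * sum(P * T_) + smooth
  den <- sum(P) + sum(T_) + smooth
  -(2 * T_ * den - num) / den^2
}

#' Documented voxelwise Dice gradient expression
#'
#' Evaluates `2 * T * (T^2 - P^2) / (T^2 + P^2)` voxelwise, with the limit
#' convention of 0 where `T = P = 0`. This is the voxelwise derivative of
#' the squared-denominator Dice coefficient `2PT / (P^2 + T^2)` rescaled by
#' the positive factor `(T^2 + P^2)`; it is kept as a documented reference
#' form rather than used for optimization.
#'
#' @param P probability volume.
#' @param T_ binary mask.
#' @return array of the same shape as `P`.
#' @export
dice_loss_grad_reference <- function(P, T_) {
  if (length(P) != length(T_)) stop("P and T must have the same shape")
  den <- T_^2 + P^2
  out <- ifelse(den == 0, 0, 2 * T_ * (T_^2 - P^2) / ifelse(den == 0, 1, den))
  if (!is.null(dim(P))) dim(out) <- dim(P)
  out
}

# Voxelwise derivative of the squared-denominator Dice coefficient
# d/dP [ 2PT / (P^2 + T^2) ] = 2T(T^2 - P^2) / (T^2 + P^2)^2; 0 at T = P = 0.
dice_squared_coeff_grad <- function(P, T_) {
  den <- T_^2 + P^2
  out <- ifelse(den == 0, 0, 2 * T_ * (T_^2 - P^2) / ifelse(den == 0, 1, den)^2)
  if (!is.null(dim(P))) dim(out) <- dim(P)
  out
}

#' Summed binary cross-entropy loss
#'
#' `-sum(T * log(P) + (1 - T) * log(1 - P))` over all voxels (a sum, not a
#' mean). Probabilities are clipped to `[eps, 1 - eps]`. The gradient with
#' respect to the pre-sigmoid activation is `P - T` voxelwise.
#'
#' @param P probability volume in `[0, 1]`.
#' @param T_ binary mask of the same shape.
#' @param eps clipping constant.
#' @return scalar loss.
#' @export
bce_loss <- function(P, T_, eps = 1e-7) {
  if (length(P) != length(T_)) stop("P and T must have the same shape")
  P <- pmin(pmax(as.numeric(P), eps), 1 - eps)
  T_ <- as.numeric(T_)
  -sum(T_ * log(P) + (1 - T_) * log(1 - P))
}

#' Mean negative log-likelihood for class probabilities
#'
#' Mean over the batch of `-ln` of the probability assigned to the true
#' class. Zero probabilities at the true class are clipped with a warning.
#'
#' @param P matrix (n x 2) of class probability vectors, or a single
#'   2-vector.
#' @param T_ one-hot matrix of the same shape, or a class index vector
#'   (1-based) of length n.
#' @param eps clipping constant.
#' @return scalar loss.
#' @export
nll_loss <- function(P, T_, eps = 1e-12) {
  if (is.null(dim(P))) P <- matrix(P, nrow = 1)
  if (is.null(dim(T_))) {
    if (length(T_) == nrow(P)) {
      oh <- matrix(0, nrow(P), ncol(P))
      oh[cbind(seq_len(nrow(P)), as.integer(T_))] <- 1
      T_ <- oh
    } else {
      T_ <- matrix(T_, nrow = 1)
    }
  }
  stopifnot(nrow(P) >= 1, identical(dim(P), dim(T_)))
  ptrue <- rowSums(P * T_)
  if (any(ptrue <= 0)) {
    warning("zero probability at the true class; clipped")
    ptrue <- pmax(ptrue, eps)
  }
  mean(-log(ptrue))
}
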