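#' @title Soft-Dice loss, Dice coefficient, lesion size, rank-sum test
#' @name losses_metrics
NULL

.DICE_EPS <- 1e-7

.as_arr <- function(x) if (is.list(x)) x$data else x

#' Soft Dice coefficient
#'
#' \deqn{D(p) = \frac{2 \sum_i p_i r_i}{\sum_i p_i^2 + \sum_i r_i^2 + \epsilon}}
#' with a small guard `eps` in the denominator so empty targets do not
#' divide by zero. On binary `p` this equals the classical
#' `2TP / (2TP + FP + FN)` coefficient.
#'
#' @param p soft prediction array, values in `[0, 1]`.
#' @param r binary target of the same shape.
#' @param eps denominator guard; default 1e-7.
#' @return Scalar in `[0, 1]`.
#' @export
soft_dice <- function(p, r, eps = .DICE_EPS) {
  p <- .as_arr(p); r <- .as_arr(r)
  if (!identical(dim(p), dim(r)) || length(p) != length(r))
    stopf("soft_dice: shapes differ")
  2 * sum(p * r) / (sum(p * p) + sum(r * r) + eps)
}

# dD(p; r)/dp
.soft_dice_grad <- function(p, r, eps = .DICE_EPS) {
  S <- sum(p * p) + sum(r * r) + eps
  Spr <- sum(p * r)
  (2 * r * S - 4 * Spr * p) / (S * S)
}

#' Two-channel soft-Dice loss
#'
#' The training loss `2 - (D(p; r) + D(q; 1 - r))`: the first channel
#' predicts the lesion, the second its complement (the target is flipped
#' 0 <-> 1 for the complement term). The loss lies in `[0, 2]` and is 0
#' exactly when `p = r`.
#'
#' @param pred either a list with elements `p` and `q`, or the soft lesion
#'   channel alone (then `q = 1 - p` is implied by the softmax pairing).
#' @param r binary target array.
#' @param eps denominator guard passed to [soft_dice].
#' @return Scalar loss in `[0, 2]`.
#' @export
two_channel_loss <- function(pred, r, eps = .DICE_EPS) {
  r <- .as_arr(r)
  if (is.list(pred) && !is.null(pred$p)) {
    p <- pred$p; q <- pred$q
  } else {
    p <- pred; q <- 1 - pred
  }
  2 - soft_dice(p, r, eps) - soft_dice(q, 1 - r, eps)
}

# dL/dp for the two-channel loss with q = 1 - p
.two_channel_loss_grad <- function(p, r, eps = .DICE_EPS) {
  -.soft_dice_grad(p, r, eps) + .soft_dice_grad(1 - p, 1 - r, eps)
}

#' Dice coefficient with overlap counts
#'
#' Counts true positives, false positives and false negatives between two
#' binary masks and applies `DICE = 2TP / (2TP + FP + FN)`. Two empty masks
#' agree perfectly on the absence of lesion and score 1 by convention.
#'
#' @param pred predicted [lesion_mask] (or binary array).
#' @param truth ground-truth [lesion_mask] (or binary array).
#' @return An object of class `dice_result`: list with `TP`, `FP`, `FN`,
#'   `dice`.
#' @export
dice_coefficient <- function(pred, truth) {
  p <- .as_arr(pred); t <- .as_arr(truth)
  if (!identical(dim(p), dim(t)))
    stopf("dice_coefficient: shapes differ")
  if (!all(p %in% c(0, 1)) || !all(t %in% c(0, 1)))
    stopf("dice_coefficient: inputs must be binary")
  TP <- sum(p == 1 & t == 1)
  FP <- sum(p == 1 & t == 0)
  FN <- sum(p == 0 & t == 1)
  dice <- if (2 * TP + FP + FN == 0) 1 else 2 * TP / (2 * TP + FP + FN)
  structure(list(TP = TP, FP = FP, FN = FN, dice = dice),
            class = "dice_result")
}

#' @export
print.dice_result <- function(x, ...) {
  cat(sprintf("<dice_result> TP=%d FP=%d FN=%d dice=%.4f\n",
              x$TP, x$FP, x$FN, x$dice))
  invisible(x)
}

#' Classify a lesion as small or large from its bounding box
#'
#' The foreground bounding-box extents are measured in mm; a lesion is
#' `small` only when all three extents are strictly below the thresholds
#' (defaults 20 x 20 x 25 mm in LR x PA x IS), otherwise `large` --
#' boundary-equal lesions count as large. With multiple components the
#' whole-foreground extents are used.
#'
#' @param mask a nonempty [lesion_mask] (or binary array).
#' @param spacing mm per voxel along the canonical (IS, PA, LR) axes; taken
#'   from the mask when available.
#' @param thresholds extents in mm as `c(LR, PA, IS)`.
#' @return `"small"` or `"large"`.
#' @export
classify_lesion_size <- function(mask, spacing = NULL,
                                 thresholds = c(20, 20, 25)) {
  m <- .as_arr(mask)
  if (is.null(spacing)) spacing <- mask$spacing %||% c(1, 1, 1)
  idx <- which(m == 1, arr.ind = TRUE)
  if (nrow(idx) == 0L) stopf("classify_lesion_size: empty mask")
  ext <- (apply(idx, 2, max) - apply(idx, 2, min) + 1) * spacing
  # array axes are (IS, PA, LR); thresholds arrive as (LR, PA, IS)
  thr <- thresholds[c(3, 2, 1)]
  if (all(ext < thr)) "small" else "large"
}

#' Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' Two-sided p-value for the difference between two samples: the exact
#' rank-sum null distribution is enumerated when the combined sample size
#' is at most 12 and there are no ties; otherwise the normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param x,y nonempty numeric samples.
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stopf("wilcoxon_rank_sum: both samples must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- (length(x) + length(y) <= 12L) && !ties
  suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                correct = TRUE)$p.value
  )
}
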