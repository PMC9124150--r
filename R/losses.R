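#' Soft Dice and IOU overlap
#'
#' Differentiable relaxations of the Dice similarity coefficient
#' `2|A∩B| / (|A|+|B|)` and the intersection-over-union `|A∩B| / |A∪B|`:
#' set sizes are replaced by sums of products of the binary target with
#' the soft prediction, smoothed by `epsilon` in numerator and
#' denominator. On binary predictions with `epsilon -> 0` these reduce to
#' the set-based scores.
#'
#' @param y binary target array.
#' @param yhat soft prediction in \[0, 1\], same shape as `y`.
#' @param epsilon positive smoothing constant (default 1).
#' @return `list(dsc, iou)`, both in \[0, 1\].
#' @export
soft_overlap <- function(y, yhat, epsilon = 1) {
  check_loss_args(y, yhat, epsilon)
  inter <- sum(y * yhat)
  sy <- sum(y); sp <- sum(yhat)
  list(dsc = (2 * inter + epsilon) / (sy + sp + epsilon),
       iou = (inter + epsilon) / (sy + sp - inter + epsilon))
}

#' Compound IOU + Dice loss
#'
#' `2 - (IOU + DSC)` over the soft overlap terms: 0 for perfect overlap of
#' non-empty masks, 2 for disjoint non-empty masks.
#'
#' @inheritParams soft_overlap
#' @return A list of class `"loss_breakdown"` with `total`, `iou_term` and
#'   `dice_term`.
#' @export
loss_iou_dsc <- function(y, yhat, epsilon = 1) {
  ov <- soft_overlap(y, yhat, epsilon)
  structure(list(total = 2 - (ov$iou + ov$dsc), dice_term = ov$dsc,
                 iou_term = ov$iou, bce_term = NA_real_),
            class = "loss_breakdown")
}

#' Compound Dice + binary cross-entropy loss
#'
#' Sum of the soft Dice loss `1 - DSC` and the mean per-voxel binary
#' cross-entropy. Predictions are clamped to `[1e-7, 1 - 1e-7]` before the
#' logarithms.
#'
#' @inheritParams soft_overlap
#' @return A list of class `"loss_breakdown"` with `total`, `dice_term`
#'   (the Dice loss `1 - DSC`) and `bce_term`.
#' @export
loss_dice_bce <- function(y, yhat, epsilon = 1) {
  check_loss_args(y, yhat, epsilon)
  p <- pmin(pmax(yhat, 1e-7), 1 - 1e-7)
  bce <- -mean(y * log(p) + (1 - y) * log(1 - p))
  dsc <- soft_overlap(y, yhat, epsilon)$dsc
  structure(list(total = (1 - dsc) + bce, dice_term = 1 - dsc,
                 bce_term = bce, iou_term = NA_real_),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("loss total %.6f (dice %.6f, bce %s, iou %s)\n", x$total,
              x$dice_term,
              if (is.na(x$bce_term)) "-" else sprintf("%.6f", x$bce_term),
              if (is.na(x$iou_term)) "-" else sprintf("%.6f", x$iou_term)))
  invisible(x)
}

check_loss_args <- function(y, yhat, epsilon) {
  if (!identical(dim(y), dim(yhat)) && length(y) != length(yhat)) {
    stop("target and prediction shapes differ", call. = FALSE)
  }
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  if (min(yhat) < 0 || max(yhat) > 1) {
    stop("soft predictions must lie in [0, 1]", call. = FALSE)
  }
  invisible(NULL)
}

# ---- analytic gradients used by the trainer --------------------------------

# Returns list(value, grad) of the selected compound loss with respect to
# the prediction array.
loss_with_grad <- function(y, p, loss = c("eq6", "eq1"), epsilon = 1) {
  loss <- match.arg(loss)
  n <- length(p)
  inter <- sum(y * p)
  sy <- sum(y); sp <- sum(p)
  if (loss == "eq6") {
    pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
    bce <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
    den <- sy + sp + epsilon
    dsc <- (2 * inter + epsilon) / den
    gdsc <- (2 * y * den - (2 * inter + epsilon)) / den^2
    gbce <- (pc - y) / (pc * (1 - pc)) / n
    list(value = (1 - dsc) + bce, grad = -gdsc + gbce)
  } else {
    den_d <- sy + sp + epsilon
    dsc <- (2 * inter + epsilon) / den_d
    gdsc <- (2 * y * den_d - (2 * inter + epsilon)) / den_d^2
    u <- sy + sp - inter + epsilon
    iou <- (inter + epsilon) / u
    giou <- (y * u - (inter + epsilon) * (1 - y)) / u^2
    list(value = 2 - (iou + dsc), grad = -(giou + gdsc))
  }
}
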