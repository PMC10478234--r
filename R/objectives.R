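#' Training schedule configuration
#'
#' Piecewise-constant learning-rate and deep-supervision-weight schedules.
#' At the default 180 epochs the pieces are exactly the published training
#' recipe: learning rate 1e-5 on epochs `[0, 100)`, 1e-6 on `[100, 160)`,
#' 1e-7 on `[160, 180]`; supervision weight alpha = 0.8^k on the five
#' 40-epoch intervals starting at 0, 40, 80, 120, 160. For a different epoch
#' budget the interval boundaries scale proportionally (rounded), keeping
#' the same rate/alpha values; `lr_scale` multiplies all learning rates (the
#' desk preset uses a larger rate to make a short CPU run converge).
#'
#' @param epochs Total training epochs (default 180).
#' @param lr_scale Multiplier applied to the three learning rates
#'   (default 1).
#' @param weight_decay L2 weight decay factor (default 5e-4).
#' @param batch_size Mini-batch size (default 3).
#' @return An object of class `schedule_config`.
#' @export
schedule_config <- function(epochs = 180L, lr_scale = 1, weight_decay = 5e-4,
                            batch_size = 3L) {
  epochs <- as.integer(epochs)
  if (epochs < 1L) cx_stop("bad_schedule", "epochs must be >= 1")
  sc <- epochs / 180
  lr_b <- unique(pmin(round(c(0, 100, 160) * sc), epochs))
  lr_v <- c(1e-5, 1e-6, 1e-7)[seq_along(lr_b)] * lr_scale
  al_b <- unique(pmin(round(c(0, 40, 80, 120, 160) * sc), epochs))
  al_v <- 0.8^(seq_along(al_b) - 1)
  structure(list(epochs = epochs,
                 lr_bounds = lr_b, lr_values = lr_v,
                 alpha_bounds = al_b, alpha_values = al_v,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size)),
            class = "schedule_config")
}

piecewise_at <- function(epoch, bounds, values, epochs) {
  if (epoch < 0 || epoch > epochs)
    cx_stop("epoch_range", sprintf("epoch %s outside [0, %d]", epoch, epochs))
  values[findInterval(epoch, bounds)]
}

#' Deep-supervision weight at an epoch
#'
#' Intervals are half-open on the left (`[lo, hi)`), with the final interval
#' closed at `epochs`.
#'
#' @param epoch Integer in `[0, epochs]`.
#' @param sched A [schedule_config()].
#' @return The alpha of the containing interval.
#' @export
alpha_at_epoch <- function(epoch, sched = schedule_config()) {
  piecewise_at(epoch, sched$alpha_bounds, sched$alpha_values, sched$epochs)
}

#' Learning rate at an epoch
#'
#' @inheritParams alpha_at_epoch
#' @return The learning rate of the containing interval.
#' @export
lr_at_epoch <- function(epoch, sched = schedule_config()) {
  piecewise_at(epoch, sched$lr_bounds, sched$lr_values, sched$epochs)
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(pred * gt) + smooth) / (sum(pred) + sum(gt) + smooth)`.
#' The smoothing constant keeps the loss defined on empty masks.
#'
#' @param pred Foreground-probability grid (values in `[0, 1]`).
#' @param gt Binary ground-truth grid (or [label_mask]) of the same shape.
#' @param smooth Smoothing constant (default 1e-5).
#' @return Loss in `[0, 1]`; 0 means perfect overlap.
#' @export
dice_loss <- function(pred, gt, smooth = 1e-5) {
  p <- vox(pred); g <- vox(gt)
  if (!identical(dim(p), dim(g)))
    cx_stop("shape_mismatch", "pred and gt must have identical shapes")
  1 - (2 * sum(p * as.numeric(g)) + smooth) / (sum(p) + sum(g) + smooth)
}

# Gradient of dice_loss w.r.t. pred, as an array of pred's shape.
dice_loss_grad <- function(pred, gt, smooth = 1e-5) {
  p <- vox(pred); g <- as.numeric(vox(gt))
  num <- 2 * sum(p * g) + smooth
  den <- sum(p) + sum(g) + smooth
  out <- -(2 * g * den - num) / den^2
  dim(out) <- dim(p)
  out
}

#' Composite deep-supervision loss
#'
#' The full-resolution loss plus a down-weighted sum of the auxiliary
#' decoder losses: `L1 + alpha * (L2 + L3 + L4)`.
#'
#' @param losses Numeric vector `(L1, L2, L3, L4)` (or `L1` alone when deep
#'   supervision is off); all non-negative.
#' @param alpha Supervision weight in `(0, 1]`.
#' @return The scalar total loss.
#' @export
deep_supervision_loss <- function(losses, alpha) {
  if (any(losses < 0)) cx_stop("bad_loss", "losses must be non-negative")
  if (alpha <= 0 || alpha > 1) cx_stop("bad_loss", "alpha must be in (0, 1]")
  losses[1] + if (length(losses) > 1) alpha * sum(losses[-1]) else 0
}
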