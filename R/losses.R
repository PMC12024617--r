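# Training losses: Dice on event probabilities, MAE + Pearson-correlation on
# scaled SpO2, and their weighted sum.

#' Scale an SpO2 trace to the unit interval
#'
#' Lower-bound-truncated linear scaling `max(y - 80, 0) / 20`, mapping the
#' clinically relevant 80-100% range onto `[0, 1]`.
#'
#' @param y SpO2 trace in percent.
#' @return Scaled trace in `[0, 1]`.
#' @export
scale_spo2 <- function(y) {
  pmax(y - 80, 0) / 20
}

#' Map a scaled SpO2 prediction back to percent
#'
#' @param p Scaled trace in `[0, 1]`.
#' @return SpO2 in percent, `80 + 20 p`.
#' @export
inv_scale_spo2 <- function(p) {
  80 + 20 * p
}

#' Dice coefficient loss
#'
#' `1 - (2 sum(pred * target) + eps) / (sum(pred) + sum(target) + eps)`,
#' robust to the heavy class imbalance of rare events.
#'
#' @param pred Predicted probabilities in `[0, 1]`.
#' @param target Binary (or soft) targets, same length.
#' @param eps Smoothing factor for numerical stability.
#' @return Scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(pred, target, eps = 1e-4) {
  if (length(pred) != length(target)) stop_invalid("length mismatch")
  1 - (2 * sum(pred * target) + eps) / (sum(pred) + sum(target) + eps)
}

#' Composite SpO2 loss: MAE plus Pearson-correlation loss
#'
#' `mean(|pred - target|) + lambda_corr * (1 - cor(pred, target))`. When either
#' input has zero variance the correlation is defined as 0 (the term then
#' contributes `lambda_corr`), so a mean-collapsed prediction is penalised
#' rather than silently passing.
#'
#' @param pred,target Scaled SpO2 traces, length >= 2.
#' @param lambda_corr Weight of the correlation term.
#' @return Scalar loss.
#' @export
spo2_loss <- function(pred, target, lambda_corr = 1) {
  if (length(pred) != length(target)) stop_invalid("length mismatch")
  if (length(pred) < 2) stop_invalid("need at least two samples")
  mae <- mean(abs(pred - target))
  a <- pred - mean(pred)
  b <- target - mean(target)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  rho <- if (na == 0 || nb == 0) 0 else sum(a * b) / (na * nb)
  mae + lambda_corr * (1 - rho)
}

#' Total multitask loss
#'
#' `L_dice + lambda_spo2 * L_spo2`; the weights default to 1, and the SpO2
#' term is dropped entirely for the single-task (no SpO2 branch) variant.
#'
#' @param l_dice Event Dice loss.
#' @param l_spo2 SpO2 composite loss (NULL for the single-task variant).
#' @param lambda_spo2 Weight of the SpO2 loss.
#' @return Scalar loss.
#' @export
total_loss <- function(l_dice, l_spo2 = NULL, lambda_spo2 = 1) {
  if (is.null(l_spo2)) l_dice else l_dice + lambda_spo2 * l_spo2
}

# analytic gradients used by the trainer -------------------------------------

dice_loss_grad <- function(pred, target, eps = 1e-4) {
  num <- 2 * sum(pred * target) + eps
  den <- sum(pred) + sum(target) + eps
  -(2 * target * den - num) / den^2
}

spo2_loss_grad <- function(pred, target, lambda_corr = 1) {
  n <- length(pred)
  g <- sign(pred - target) / n
  a <- pred - mean(pred)
  b <- target - mean(target)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na > 0 && nb > 0) {
    rho <- sum(a * b) / (na * nb)
    g <- g - lambda_corr * (b / (na * nb) - rho * a / na^2)
  }
  g
}
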