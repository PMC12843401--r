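# Compound training objective: L_total = lambda1 * L_CE + lambda2 * L_Dice,
# with lambda1 = lambda2 = 0.5 by default. Cross-entropy supplies smooth
# per-pixel gradients; Dice directly optimizes foreground overlap and
# counteracts class imbalance.

#' Loss configuration
#'
#' @param lambda_ce,lambda_dice nonnegative weights of the cross-entropy and
#'   Dice terms (both 0.5 by default).
#' @param smooth additive smoothing constant of the Dice term.
#' @param exclude_background drop class 0 from the Dice average (the Dice
#'   term always averages over the `C - 1` foreground classes when `TRUE`).
#' @return a `loss_config` list.
#' @export
loss_config <- function(lambda_ce = 0.5, lambda_dice = 0.5, smooth = 1e-5,
                        exclude_background = TRUE) {
  stopifnot(lambda_ce >= 0, lambda_dice >= 0, smooth > 0)
  structure(list(lambda_ce = lambda_ce, lambda_dice = lambda_dice,
                 smooth = smooth, exclude_background = exclude_background),
            class = "loss_config")
}

# Coerce predictions/targets to N x C matrices in token order.
as_prob_matrix <- function(p) {
  if (is.matrix(p)) return(p)
  d <- dim(p)
  if (length(d) == 3) {
    tk <- aperm(p, c(2, 1, 3))
    dim(tk) <- c(d[1] * d[2], d[3])
    return(tk)
  }
  stop("probabilities must be an N x C matrix or (H, W, C) array")
}

#' One-hot encode an integer label mask
#'
#' @param mask integer matrix (labels `0 .. num_classes - 1`) or an already
#'   one-hot `N x C` matrix (returned unchanged).
#' @param num_classes class count C.
#' @return `N x C` one-hot matrix in row-major token order.
#' @export
to_onehot <- function(mask, num_classes) {
  if (is.matrix(mask) && ncol(mask) == num_classes &&
      all(mask %in% c(0, 1)) && all(rowSums(mask) == 1)) return(mask)
  if (any(mask < 0 | mask >= num_classes))
    stop("mask labels must lie in [0, num_classes)")
  v <- as.vector(t(mask))  # token order: (row-1)*W + col
  oh <- matrix(0, length(v), num_classes)
  oh[cbind(seq_along(v), v + 1L)] <- 1
  oh
}

#' Cross-entropy loss over a probability map
#'
#' `-(1/N) * sum_i sum_c y_ic log p_ic`. Probabilities are clamped away from
#' zero so a confident wrong prediction yields a large finite value, never
#' `NaN`.
#'
#' @param p per-pixel class probabilities, `N x C` matrix or `(H, W, C)`
#'   array (rows summing to 1).
#' @param y integer label mask or one-hot matrix matching `p`.
#' @param clamp lower clamp applied to `p` before the logarithm.
#' @return nonnegative scalar.
#' @examples
#' p <- matrix(c(0.8, 0.2, 0.4, 0.6), 2, byrow = TRUE)
#' y <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
#' ce_loss(p, y)  # -(log(0.8) + log(0.6)) / 2
#' @export
ce_loss <- function(p, y, clamp = 1e-12) {
  pm <- as_prob_matrix(p)
  yh <- to_onehot(y, ncol(pm))
  if (nrow(yh) != nrow(pm)) stop("p and y disagree in pixel count")
  -sum(yh * log(pmax(pm, clamp))) / nrow(pm)
}

#' Dice loss over the foreground classes
#'
#' `1 - (1/(C-1)) * sum_{c>=1} (2 * sum_i p_ic y_ic + s) /
#' (sum_i p_ic + sum_i y_ic + s)`; class 0 (background) is excluded from the
#' average, `s` is the smoothing constant.
#'
#' @inheritParams ce_loss
#' @param cfg a [loss_config()].
#' @return scalar in `[0, 1]` (up to smoothing).
#' @export
dice_loss <- function(p, y, cfg = loss_config()) {
  pm <- as_prob_matrix(p)
  C <- ncol(pm)
  if (C < 2 && cfg$exclude_background)
    stop("dice_loss requires at least one foreground class (C >= 2)")
  yh <- to_onehot(y, C)
  cls <- if (cfg$exclude_background) 2:C else 1:C
  inter <- colSums(pm * yh)[cls]
  psum <- colSums(pm)[cls]
  ysum <- colSums(yh)[cls]
  dice <- (2 * inter + cfg$smooth) / (psum + ysum + cfg$smooth)
  1 - mean(dice)
}

#' Compound segmentation loss
#'
#' `lambda_ce * CE + lambda_dice * Dice` (both weights 0.5 by default).
#'
#' @inheritParams dice_loss
#' @return scalar; attributes `"ce"` and `"dice"` carry the two components.
#' @export
total_loss <- function(p, y, cfg = loss_config()) {
  ce <- ce_loss(p, y)
  di <- dice_loss(p, y, cfg)
  structure(cfg$lambda_ce * ce + cfg$lambda_dice * di, ce = ce, dice = di)
}

# Differentiable Dice loss from a probability-token node (training path).
ag_dice_loss <- function(probs, y_onehot, smooth = 1e-5) {
  C <- ncol(y_onehot)
  cls <- 2:C
  inter <- ag_subset(ag_colsums(ag_mul(probs, y_onehot)), cls)
  psum <- ag_subset(ag_colsums(probs), cls)
  ysum <- colSums(y_onehot)[cls]
  dice <- ag_div(ag_add(ag_scale(inter, 2), smooth),
                 ag_add(ag_add(psum, ysum), smooth))
  ag_sub(1, ag_mean(dice))
}

# Training loss from logits tokens (N x C): fused CE + Dice on softmax probs.
ag_total_loss <- function(logits, y_onehot, cfg = loss_config()) {
  ce <- ag_ce_logits(logits, y_onehot)
  probs <- ag_softmax_rows(logits)
  di <- ag_dice_loss(probs, y_onehot, smooth = cfg$smooth)
  list(total = ag_add(ag_scale(ce, cfg$lambda_ce), ag_scale(di, cfg$lambda_dice)),
       ce = vof(ce), dice = vof(di))
}
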