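# Segmentation losses: voxel-wise cross-entropy plus soft multi-class Dice
# over the foreground classes, with analytic gradients w.r.t. the scores.

softmax_classes <- function(scores) {
  d <- dim(scores)
  mx <- scores[, , 1, , drop = FALSE]
  if (d[3] > 1) for (c in 2:d[3]) mx <- pmax(mx, scores[, , c, , drop = FALSE])
  p <- array(0, dim = d)
  for (c in seq_len(d[3])) p[, , c, ] <- exp(scores[, , c, , drop = FALSE] - mx)
  tot <- p[, , 1, , drop = FALSE]
  if (d[3] > 1) for (c in 2:d[3]) tot <- tot + p[, , c, , drop = FALSE]
  for (c in seq_len(d[3])) p[, , c, ] <- p[, , c, , drop = FALSE] / tot
  p
}

onehot_classes <- function(target, n_classes) {
  d <- dim(target)
  y <- array(0, dim = c(d[1], d[2], n_classes, d[3]))
  for (c in seq_len(n_classes)) y[, , c, ] <- (target == c - 1L)
  y
}

#' Segmentation loss and its score gradient
#'
#' `loss = CE + dice_weight * (1 - mean_c softDice_c)` where the soft Dice
#' runs over the foreground classes `1..num_classes-1` with +1 smoothing in
#' numerator and denominator (matching the smoothed evaluation Dice).
#'
#' @param scores network output, array (H, W, C, N).
#' @param target integer array (H, W, N) with values `0..C-1`.
#' @param loss_name `"ce_dice"`, `"ce"` or `"dice"`.
#' @param dice_weight weight of the Dice term in `"ce_dice"`.
#' @return list with `loss` (scalar) and `grad` (same shape as scores).
#' @export
seg_loss <- function(scores, target, loss_name = "ce_dice",
                     dice_weight = 1) {
  d <- dim(scores)
  nC <- d[3]
  npix <- d[1] * d[2] * d[4]
  p <- softmax_classes(scores)
  y <- onehot_classes(target, nC)
  use_ce <- loss_name %in% c("ce", "ce_dice")
  use_dice <- loss_name %in% c("dice", "ce_dice")
  if (!use_ce && !use_dice) stop("unknown loss_name: ", loss_name)
  w_dice <- if (loss_name == "dice") 1 else dice_weight
  loss <- 0
  grad_s <- array(0, dim = d)
  if (use_ce) {
    p_true <- apply_sum_classes(p * y)
    loss <- loss - sum(log(pmax(p_true, 1e-12))) / npix
    grad_s <- grad_s + (p - y) / npix
  }
  if (use_dice) {
    gp <- array(0, dim = d)
    n_fg <- nC - 1L
    dl <- 0
    for (c in 2:nC) {
      pc <- p[, , c, , drop = FALSE]
      yc <- y[, , c, , drop = FALSE]
      sp <- sum(pc); sy <- sum(yc); spy <- sum(pc * yc)
      denom <- sp + sy + 1
      dice_c <- (2 * spy + 1) / denom
      dl <- dl + (1 - dice_c) / n_fg
      # d dice_c / d pc = (2*yc*denom - (2*spy+1)) / denom^2
      gp[, , c, ] <- -(2 * yc * denom - (2 * spy + 1)) / denom^2 / n_fg
    }
    loss <- loss + w_dice * dl
    # chain rule through the softmax: gs = p * (gp - sum_c gp_c p_c)
    dot <- array(0, dim = c(d[1], d[2], 1, d[4]))
    for (c in seq_len(nC)) dot <- dot + gp[, , c, , drop = FALSE] * p[, , c, , drop = FALSE]
    gs <- array(0, dim = d)
    for (c in seq_len(nC))
      gs[, , c, ] <- p[, , c, , drop = FALSE] *
        (gp[, , c, , drop = FALSE] - dot)
    grad_s <- grad_s + w_dice * gs
  }
  list(loss = loss, grad = grad_s)
}

# sum over the class axis of an (H, W, C, N) array -> (H, W, 1, N)
apply_sum_classes <- function(a) {
  d <- dim(a)
  out <- a[, , 1, , drop = FALSE]
  if (d[3] > 1) for (c in 2:d[3]) out <- out + a[, , c, , drop = FALSE]
  out
}
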