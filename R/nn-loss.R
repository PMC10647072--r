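#' Multi-label soft Dice loss
#'
#' Trains all three output channels (background, MS, MSA) simultaneously:
#' for each channel the soft Dice score
#' \deqn{s_c = (2 \sum p t + \epsilon) / (\sum p + \sum t + \epsilon)}
#' is computed over every voxel (and batch sample), with smoothing
#' `eps = 1` in numerator and denominator, and the loss is
#' `1 - mean(s_c)` over the channels. The loss is 0 exactly when the
#' prediction equals the truth on all channels (up to the epsilon smoothing)
#' and is invariant under any voxel permutation applied jointly to
#' prediction and truth.
#'
#' @param pred probabilities in \[0, 1\]: a `tpl_prob_volume`, or an array
#'   whose channel axis is given by `channel_axis`.
#' @param truth matching binary labels: a `tpl_labels`, or an array shaped
#'   like `pred`.
#' @param channel_axis which array axis indexes the channels; defaults to
#'   the last axis for bare arrays.
#' @param eps smoothing constant.
#' @return scalar loss in \[0, 1\].
#' @export
multi_label_dice_loss <- function(pred, truth, channel_axis = NULL, eps = 1) {
  arrs <- .loss_arrays(pred, truth, channel_axis)
  .dice_loss(arrs$pred, arrs$truth, arrs$axis, eps)$loss
}

.loss_arrays <- function(pred, truth, channel_axis) {
  if (inherits(pred, "tpl_prob_volume")) {
    channel_axis <- 4L
    pred <- pred$data
  }
  if (inherits(truth, "tpl_labels")) {
    ch <- truth$channels
    truth <- array(c(ch$background, ch$ms, ch$msa), c(dim(ch$ms), 3L))
  }
  if (is.null(channel_axis)) channel_axis <- length(dim(pred))
  if (!identical(dim(pred), dim(truth)))
    stop("prediction and truth shapes (and channels) must match", call. = FALSE)
  list(pred = pred, truth = truth, axis = channel_axis)
}

# loss + gradient wrt pred; channel axis `ax`. Sums run over all other axes.
# The engine always calls this with ax = last axis (cheap column view).
.dice_loss <- function(pred, truth, ax, eps = 1) {
  d <- dim(pred)
  nc <- d[ax]
  if (ax == length(d)) {
    p <- pred; t <- truth
    dim(p) <- c(prod(d) / nc, nc); dim(t) <- dim(p)
  } else {
    perm <- c(setdiff(seq_along(d), ax), ax)
    p <- matrix(aperm(pred, perm), ncol = nc)
    t <- matrix(aperm(truth, perm), ncol = nc)
  }
  num <- 2 * colSums(p * t) + eps
  den <- colSums(p) + colSums(t) + eps
  s <- num / den
  loss <- 1 - mean(s)
  # d loss / d p_c = -(1/nc) * (2 t_c * den_c - num_c) / den_c^2
  gmat <- p  # reuse shape
  for (ch in seq_len(nc))
    gmat[, ch] <- (-1 / nc) * (2 * t[, ch] * den[ch] - num[ch]) / (den[ch]^2)
  if (ax == length(d)) {
    grad <- gmat; dim(grad) <- d
  } else {
    grad <- aperm(array(gmat, d[perm]), order(perm))
  }
  list(loss = loss, grad = grad, per_channel = s)
}
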