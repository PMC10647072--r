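#' Training configuration
#'
#' Adam with an initial learning rate of 0.001, reduced on a validation-loss
#' plateau by a factor of 0.5 with a patience of 5 epochs, over 200 epochs by
#' default (desk-scale runs shorten this). Batch size defaults to 8 for 2D
#' networks and is fixed at 1 for volumetric networks. Augmentation draws a
#' rotation in +/-20 degrees and a brightness factor in +/-20% per training
#' sample per epoch. Every source of randomness (weight init, shuffling,
#' augmentation) derives from `seed`, so identical configurations reproduce
#' identical loss histories.
#'
#' @param epochs number of epochs.
#' @param initial_lr initial Adam learning rate.
#' @param lr_factor multiplicative reduction on plateau, in (0, 1).
#' @param lr_patience epochs without relative improvement (> 1e-4) of the
#'   monitored loss before the learning rate is reduced.
#' @param batch_size samples per step; `NULL` = 8 for 2D, 1 for 3D.
#' @param augment enable rotation/brightness augmentation.
#' @param rotation_range,brightness_range augmentation half-ranges.
#' @param seed master RNG seed.
#' @return a `tpl_train_config`.
#' @export
train_config <- function(epochs = 200L, initial_lr = 0.001, lr_factor = 0.5,
                         lr_patience = 5L, batch_size = NULL, augment = TRUE,
                         rotation_range = 20, brightness_range = 0.2,
                         seed = 1L) {
  if (lr_factor <= 0 || lr_factor >= 1) stop("lr_factor must be in (0,1)", call. = FALSE)
  if (lr_patience < 1L) stop("lr_patience must be >= 1", call. = FALSE)
  if (!is.null(batch_size) && batch_size < 1L)
    stop("batch_size must be >= 1", call. = FALSE)
  structure(list(epochs = as.integer(epochs), initial_lr = initial_lr,
                 lr_factor = lr_factor, lr_patience = as.integer(lr_patience),
                 batch_size = batch_size, augment = isTRUE(augment),
                 rotation_range = rotation_range,
                 brightness_range = brightness_range, seed = as.integer(seed)),
            class = "tpl_train_config")
}

# stack [H, W, C] samples into one [H, W, N, C] batch (channels last)
.stack_batch <- function(samples, field) {
  d <- dim(samples[[1]][[field]])
  stopifnot(length(d) == 3L)
  out <- array(0, c(d[1], d[2], length(samples), d[3]))
  for (i in seq_along(samples)) out[, , i, ] <- samples[[i]][[field]]
  out
}

.adam_step <- function(params, grads, state, lr, t, b1 = 0.9, b2 = 0.999,
                       eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    mhat <- state$m[[nm]] / (1 - b1^t)
    vhat <- state$v[[nm]] / (1 - b2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

.eval_loss <- function(model, samples, batch_size) {
  if (length(samples) == 0L) return(NA_real_)
  total <- 0
  idx <- split(seq_along(samples), ceiling(seq_along(samples) / batch_size))
  for (b in idx) {
    if (model$rank == 2L) {
      xb <- .stack_batch(samples[b], "x")
      yb <- .stack_batch(samples[b], "y")
    } else {
      xb <- samples[[b]]$x; yb <- samples[[b]]$y
    }
    fw <- .forward(model$graph, model$params, xb, want_cache = FALSE,
                   buffers = model$buffers)
    total <- total + .dice_loss(fw$out, yb, 4L)$loss * length(b)
  }
  total / length(samples)
}

#' Train a segmentation model
#'
#' Minimizes the multi-label soft Dice loss with Adam, shuffling and
#' augmenting the training samples every epoch, evaluating the validation
#' loss after each epoch, and halving the learning rate when the monitored
#' loss (validation when available, else training) plateaus. The parameters
#' with the best monitored loss are kept ("best checkpoint").
#'
#' @param net a [net_config()] or an already-built `tpl_model` (whose
#'   weights become the starting point).
#' @param data list with `train` (non-empty) and optionally `val`, each a
#'   list of samples `list(x = , y = )`: for 2D nets `x` is `[H, W, 1]` and
#'   `y` is `[H, W, 3]`; for 3D nets `[D1, D2, D3, 1]` / `[D1, D2, D3, 3]`.
#' @param cfg a [train_config()].
#' @param freeze_weights diagnostic switch: run the full loop (loss,
#'   scheduler, history) without updating any weights, which forces a
#'   non-improving loss and exercises the plateau schedule.
#' @return a `tpl_model` with elements `history` (data.frame epoch,
#'   train_loss, val_loss, lr - the lr in effect during that epoch) and
#'   `best_loss`.
#' @export
train_model <- function(net, data, cfg = train_config(), freeze_weights = FALSE) {
  stopifnot(inherits(cfg, "tpl_train_config"))
  if (is.null(data$train) || length(data$train) == 0L)
    stop("training set must contain at least one sample", call. = FALSE)
  model <- if (inherits(net, "tpl_model")) net
    else build_model(net, seed = cfg$seed)
  rank <- model$rank
  batch_size <- cfg$batch_size %||% (if (rank == 2L) 8L else 1L)
  if (rank == 3L) batch_size <- 1L
  has_val <- !is.null(data$val) && length(data$val) > 0L
  n <- length(data$train)
  .with_seed(cfg$seed + 1L, {
    state <- list(m = lapply(model$params, function(p) p * 0),
                  v = lapply(model$params, function(p) p * 0))
    lr <- cfg$initial_lr
    best <- Inf; wait <- 0L; tstep <- 0L
    best_params <- model$params
    best_buffers <- as.list(model$buffers)
    hist <- vector("list", cfg$epochs)
    for (epoch in seq_len(cfg$epochs)) {
      lr_epoch <- lr
      ord <- sample.int(n)
      ep_loss <- 0
      for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
        samples <- data$train[b]
        if (cfg$augment) {
          samples <- lapply(samples, function(s) {
            aug <- augment_pair(s$x, s$y,
                                rotation_range = cfg$rotation_range,
                                brightness_range = cfg$brightness_range)
            list(x = aug$image, y = aug$mask)
          })
        }
        if (rank == 2L) {
          xb <- .stack_batch(samples, "x")
          yb <- .stack_batch(samples, "y")
        } else {
          xb <- samples[[1]]$x; yb <- samples[[1]]$y
        }
        fw <- .forward(model$graph, model$params, xb,
                       want_cache = !freeze_weights,
                       train = !freeze_weights, buffers = model$buffers)
        dl <- .dice_loss(fw$out, yb, 4L)
        ep_loss <- ep_loss + dl$loss * length(b)
        if (!freeze_weights) {
          grads <- .backward(model$graph, model$params, fw, dl$grad)
          tstep <- tstep + 1L
          upd <- .adam_step(model$params, grads, state, lr, tstep)
          model$params <- upd$params; state <- upd$state
        }
      }
      train_loss <- ep_loss / n
      val_loss <- if (has_val) .eval_loss(model, data$val, batch_size) else NA_real_
      monitored <- if (has_val) val_loss else train_loss
      if (monitored < best * (1 - 1e-4)) {
        best <- monitored; wait <- 0L
        best_params <- model$params
        best_buffers <- as.list(model$buffers)
      } else {
        wait <- wait + 1L
        if (wait >= cfg$lr_patience) {
          lr <- lr * cfg$lr_factor
          wait <- 0L
        }
      }
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                  val_loss = val_loss, lr = lr_epoch)
    }
    model$history <- do.call(rbind, hist)
    model$best_loss <- best
    model$params <- best_params
    bb <- new.env(parent = emptyenv())
    for (nm in names(best_buffers)) assign(nm, best_buffers[[nm]], bb)
    model$buffers <- bb
    model$train_config <- cfg
    model
  })
}

#' Write / read the training history
#'
#' @param model a trained `tpl_model`.
#' @param path CSV path.
#' @export
write_history <- function(model, path) {
  stopifnot(inherits(model, "tpl_model"), !is.null(model$history))
  utils::write.csv(model$history, path, row.names = FALSE)
  invisible(path)
}
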