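#' Per-plane volumetric prediction
#'
#' Runs a 2D model over every slice of a stack and reassembles the
#' per-channel probabilities into a volume in canonical orientation, so
#' predictions from different planes can be fused voxel-by-voxel.
#'
#' @param model a trained `tpl_model` (2D family) or a [stub_model()].
#' @param stack a `tpl_slices` from [extract_slices()] on the (normalized)
#'   intensity volume.
#' @param batch_size slices per forward pass.
#' @return a `tpl_prob_volume`: `data` is `[d1, d2, d3, 3]` with channels
#'   (background, ms, msa) and `provenance` records the source plane.
#' @export
predict_plane <- function(model, stack, batch_size = 8L) {
  stopifnot(inherits(stack, "tpl_slices"))
  d <- stack$source_shape
  if (inherits(model, "tpl_stub_model")) {
    probs <- array(rep(model$value, each = prod(d)), c(d, 3L))
    return(.prob_volume(probs, stack$plane))
  }
  stopifnot(inherits(model, "tpl_model"))
  if (model$rank != 2L)
    stop("predict_plane needs a 2D model; use predict_3d for volumetric nets",
         call. = FALSE)
  sd2 <- dim(stack$slices[[1]])
  n <- length(stack$slices)
  pred_slices <- vector("list", n)
  for (b in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    xb <- array(0, c(sd2, length(b), 1L))
    for (i in seq_along(b)) xb[, , i, 1L] <- stack$slices[[b[i]]]
    fw <- .forward(model$graph, model$params, xb, want_cache = FALSE,
                   buffers = model$buffers)
    for (i in seq_along(b)) pred_slices[[b[i]]] <- fw$out[, , i, ]
  }
  probs <- array(0, c(d, 3L))
  for (ch in 1:3) {
    st <- structure(list(plane = stack$plane,
                         slices = lapply(pred_slices, function(s) s[, , ch]),
                         source_shape = d, index_axis = stack$index_axis),
                    class = "tpl_slices")
    probs[, , , ch] <- reassemble(st)$data
  }
  .prob_volume(probs, stack$plane)
}

#' Volumetric prediction
#'
#' @param model a trained 3D `tpl_model` or a [stub_model()].
#' @param v the (normalized) `tpl_volume`. Batch size is 1 by construction.
#' @return a `tpl_prob_volume` with provenance `"3d"`.
#' @export
predict_3d <- function(model, v) {
  stopifnot(inherits(v, "tpl_volume"))
  d <- dim(v$data)
  if (inherits(model, "tpl_stub_model")) {
    probs <- array(rep(model$value, each = prod(d)), c(d, 3L))
    return(.prob_volume(probs, "3d"))
  }
  stopifnot(inherits(model, "tpl_model"))
  if (model$rank != 3L)
    stop("predict_3d needs a 3D model; use predict_plane for 2D nets",
         call. = FALSE)
  x <- array(v$data, c(d, 1L))
  fw <- .forward(model$graph, model$params, x, want_cache = FALSE,
                 buffers = model$buffers)
  .prob_volume(fw$out, "3d")
}

.prob_volume <- function(data, provenance) {
  stopifnot(length(dim(data)) == 4L, dim(data)[4] == 3L,
            all(data >= 0), all(data <= 1))
  structure(list(data = data,
                 channels = c("background", "ms", "msa"),
                 provenance = provenance),
            class = "tpl_prob_volume")
}

#' @export
print.tpl_prob_volume <- function(x, ...) {
  cat(sprintf("<tpl_prob_volume> %s, channels (%s), provenance %s\n",
              paste(dim(x$data)[1:3], collapse = "x"),
              paste(x$channels, collapse = ", "), x$provenance))
  invisible(x)
}

# channel accessor for fused/derived masks
prob_channel <- function(p, name) {
  stopifnot(inherits(p, "tpl_prob_volume"))
  i <- match(name, p$channels)
  if (is.na(i)) stop("unknown channel ", name, call. = FALSE)
  p$data[, , , i]
}
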