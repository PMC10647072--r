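#' Network configuration
#'
#' Describes one member of the compact segmentation-network family. All
#' variants map a single-channel image/volume to three per-voxel sigmoid
#' channels (background, MS, MSA) - per-channel sigmoid rather than softmax,
#' because the sinus and its air region overlap and the channels are
#' therefore not mutually exclusive.
#'
#' * `unet2d`: encoder/decoder with 2x2 max-pooling, skip concatenation and
#'   2x2 transposed-convolution upsampling.
#' * `unetpp2d`: the nested variant - every skip connection passes through
#'   additional convolution blocks (dense skip pathways), giving strictly
#'   more parameters than `unet2d` at equal depth and width.
#' * `unet3d`: the 2D encoder/decoder with 3x3x3 kernels and 2x2x2 pooling.
#' * `vnet3d`: volumetric variant using strided convolutions for
#'   down-sampling, transposed convolutions for up-sampling, residual
#'   blocks, and additive attention gates on the skip pathways.
#'
#' `backbone` selects the encoder block style: `plain` (conv-relu-conv-relu),
#' `resnet_style` (residual blocks with 1x1 projection) or `densenet_style`
#' (dense concatenation inside the block); these are scaled-down stand-ins
#' for large published classification backbones, not reproductions.
#'
#' @param family one of `"unet2d"`, `"unetpp2d"`, `"unet3d"`, `"vnet3d"`.
#' @param depth number of resolution levels (>= 2).
#' @param base_filters channels at full resolution (>= 4); doubled per level.
#' @param backbone encoder block style.
#' @return a `tpl_net_config`.
#' @export
net_config <- function(family = c("unet2d", "unetpp2d", "unet3d", "vnet3d"),
                       depth = 3L, base_filters = 8L,
                       backbone = c("plain", "resnet_style", "densenet_style")) {
  family <- match.arg(family)
  backbone <- match.arg(backbone)
  depth <- as.integer(depth); base_filters <- as.integer(base_filters)
  if (depth < 2L) stop("depth must be >= 2", call. = FALSE)
  if (base_filters < 4L) stop("base_filters must be >= 4", call. = FALSE)
  structure(list(family = family, depth = depth, base_filters = base_filters,
                 backbone = backbone, in_channels = 1L, out_channels = 3L),
            class = "tpl_net_config")
}

# conv -> batch norm -> ReLU, the unit all block styles are built from
.cbr <- function(g, x, cin, cout, k = 3L, stride = 1L) {
  g_relu(g, g_bn(g, g_conv(g, x, cin, cout, k = k, stride = stride), cout))
}

# One conv block in the configured backbone style; returns the output node.
.block <- function(g, x, cin, cout, backbone) {
  if (backbone == "plain") {
    .cbr(g, .cbr(g, x, cin, cout), cout, cout)
  } else if (backbone == "resnet_style") {
    h <- .cbr(g, x, cin, cout)
    h <- g_bn(g, g_conv(g, h, cout, cout), cout)
    proj <- if (cin == cout) x else g_conv(g, x, cin, cout, k = 1L)
    g_relu(g, g_add_op(g, h, proj))
  } else {  # densenet_style
    h <- .cbr(g, x, cin, cout)
    dense <- g_concat(g, c(x, h))
    .cbr(g, dense, cin + cout, cout)
  }
}

.build_unet <- function(cfg, rank) {
  g <- .new_graph(rank)
  f <- cfg$base_filters * 2L^(0:(cfg$depth - 1L))
  x <- g_input(g)
  enc <- character(cfg$depth)
  h <- x; cin <- cfg$in_channels
  for (i in seq_len(cfg$depth)) {
    enc[i] <- .block(g, h, cin, f[i], cfg$backbone)
    if (i < cfg$depth) {
      h <- g_maxpool(g, enc[i])
      cin <- f[i]
    }
  }
  d <- enc[cfg$depth]
  for (i in rev(seq_len(cfg$depth - 1L))) {
    up <- g_upconv(g, d, f[i + 1L], f[i])
    d <- .block(g, g_concat(g, c(up, enc[i])), 2L * f[i], f[i], cfg$backbone)
  }
  head <- g_conv(g, d, f[1], cfg$out_channels, k = 1L)
  g_sigmoid(g, head)
  g
}

# Nested (dense-skip) variant: grid node X[i,j] at level i after j skip
# refinements; X[i,j] = block(concat(X[i,0..j-1], up(X[i+1,j-1]))).
.build_unetpp <- function(cfg, rank) {
  g <- .new_graph(rank)
  L <- cfg$depth
  f <- cfg$base_filters * 2L^(0:(L - 1L))
  x <- g_input(g)
  X <- matrix("", L, L)
  h <- x; cin <- cfg$in_channels
  for (i in seq_len(L)) {
    X[i, 1] <- .block(g, h, cin, f[i], cfg$backbone)
    if (i < L) {
      h <- g_maxpool(g, X[i, 1])
      cin <- f[i]
    }
  }
  for (j in 2:L) {
    for (i in seq_len(L - j + 1L)) {
      up <- g_upconv(g, X[i + 1L, j - 1L], f[i + 1L], f[i])
      ins <- c(X[i, seq_len(j - 1L)], up)
      X[i, j] <- .block(g, g_concat(g, ins), j * f[i], f[i], cfg$backbone)
    }
  }
  head <- g_conv(g, X[1, L], f[1], cfg$out_channels, k = 1L)
  g_sigmoid(g, head)
  g
}

# Additive attention gate: skip is reweighted by a sigmoid map computed from
# skip + gating signal.
.att_gate <- function(g, skip, gate, c_skip, c_mid) {
  a <- g_add_op(g, g_conv(g, skip, c_skip, c_mid, k = 1L),
                g_conv(g, gate, c_skip, c_mid, k = 1L))
  att <- g_sigmoid(g, g_conv(g, g_relu(g, a), c_mid, 1L, k = 1L))
  g_mul(g, skip, att)
}

.build_vnet <- function(cfg, rank) {
  g <- .new_graph(rank)
  L <- cfg$depth
  f <- cfg$base_filters * 2L^(0:(L - 1L))
  x <- g_input(g)
  enc <- character(L)
  h <- .cbr(g, x, cfg$in_channels, f[1])
  for (i in seq_len(L)) {
    # residual body at this level
    body <- g_bn(g, g_conv(g, g_relu(g, g_bn(g, g_conv(g, h, f[i], f[i]), f[i])),
                           f[i], f[i]), f[i])
    enc[i] <- g_relu(g, g_add_op(g, body, h))
    if (i < L)
      h <- .cbr(g, enc[i], f[i], f[i + 1L], stride = 2L)
  }
  d <- enc[L]
  for (i in rev(seq_len(L - 1L))) {
    up <- g_relu(g, g_bn(g, g_upconv(g, d, f[i + 1L], f[i]), f[i]))
    gated <- .att_gate(g, enc[i], up, f[i], max(f[i] %/% 2L, 2L))
    d <- .block(g, g_concat(g, c(up, gated)), 2L * f[i], f[i], cfg$backbone)
  }
  head <- g_conv(g, d, f[1], cfg$out_channels, k = 1L)
  g_sigmoid(g, head)
  g
}

#' Build an untrained model from a configuration
#'
#' @param cfg a [net_config()].
#' @param seed integer seed for the (He-style) weight initialization.
#' @return a `tpl_model` holding the graph, the parameter list and the
#'   configuration. Spatial input extents must be divisible by
#'   `2^(depth - 1)`.
#' @export
build_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "tpl_net_config"))
  rank <- if (cfg$family %in% c("unet2d", "unetpp2d")) 2L else 3L
  g <- switch(cfg$family,
              unet2d = .build_unet(cfg, rank),
              unetpp2d = .build_unetpp(cfg, rank),
              unet3d = .build_unet(cfg, rank),
              vnet3d = .build_vnet(cfg, rank))
  params <- .init_params(g, seed)
  structure(list(graph = g, params = params, config = cfg, rank = rank,
                 buffers = new.env(parent = emptyenv())),
            class = "tpl_model")
}

#' Number of trainable parameters
#'
#' @param model a `tpl_model`.
#' @return integer parameter count.
#' @export
n_params <- function(model) {
  stopifnot(inherits(model, "tpl_model"))
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.tpl_model <- function(x, ...) {
  cat(sprintf("<tpl_model> %s depth=%d base=%d backbone=%s | %d params, %d nodes\n",
              x$config$family, x$config$depth, x$config$base_filters,
              x$config$backbone, n_params(x), length(x$graph$nodes)))
  invisible(x)
}

#' Constant-output stub model
#'
#' Predicts the same probability everywhere; used to test the prediction and
#' fusion plumbing independently of training.
#'
#' @param value probability assigned to every voxel of every channel, or a
#'   length-3 vector (background, ms, msa).
#' @return a `tpl_stub_model`.
#' @export
stub_model <- function(value = 0.5) {
  if (length(value) == 1L) value <- rep(value, 3L)
  stopifnot(length(value) == 3L, all(value >= 0 & value <= 1))
  structure(list(value = value), class = "tpl_stub_model")
}
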