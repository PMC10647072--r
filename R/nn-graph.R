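# Static computation graph: nodes are appended in topological order by the
# network builders, evaluated forward in order and differentiated in reverse.
# Each node: list(name, op, inputs = character(), W/b = param names, attrs).

.new_graph <- function(rank) {
  g <- new.env(parent = emptyenv())
  g$rank <- rank
  g$nodes <- list()
  g$param_shapes <- list()
  g$counter <- 0L
  g
}

.g_name <- function(g, prefix) {
  g$counter <- g$counter + 1L
  paste0(prefix, g$counter)
}

.g_add <- function(g, node) {
  g$nodes[[node$name]] <- node
  node$name
}

g_input <- function(g, name = "x") .g_add(g, list(name = name, op = "input",
                                                  inputs = character()))

g_conv <- function(g, x, cin, cout, k = 3L, stride = 1L, tag = "c") {
  nm <- .g_name(g, tag)
  Wn <- paste0("W_", nm); bn <- paste0("b_", nm)
  g$param_shapes[[Wn]] <- c(k^g$rank * cin, cout)
  g$param_shapes[[bn]] <- cout
  .g_add(g, list(name = nm, op = "conv", inputs = x, W = Wn, b = bn,
                 k = as.integer(k), stride = as.integer(stride)))
}

g_upconv <- function(g, x, cin, cout, tag = "u") {
  nm <- .g_name(g, tag)
  Wn <- paste0("W_", nm); bn <- paste0("b_", nm)
  g$param_shapes[[Wn]] <- c(cin, 2L^g$rank * cout)
  g$param_shapes[[bn]] <- cout
  .g_add(g, list(name = nm, op = "upconv", inputs = x, W = Wn, b = bn))
}

# batch normalization over all non-channel axes; inference uses running stats
g_bn <- function(g, x, c) {
  nm <- .g_name(g, "n")
  Gn <- paste0("G_", nm); Bn <- paste0("B_", nm)
  g$param_shapes[[Gn]] <- c
  g$param_shapes[[Bn]] <- c
  .g_add(g, list(name = nm, op = "bn", inputs = x, G = Gn, B = Bn))
}

g_relu <- function(g, x) .g_add(g, list(name = .g_name(g, "r"), op = "relu",
                                        inputs = x))
g_sigmoid <- function(g, x) .g_add(g, list(name = .g_name(g, "s"), op = "sigmoid",
                                           inputs = x))
g_maxpool <- function(g, x) .g_add(g, list(name = .g_name(g, "p"), op = "maxpool",
                                           inputs = x))
g_concat <- function(g, xs) .g_add(g, list(name = .g_name(g, "k"), op = "concat",
                                           inputs = xs))
g_add_op <- function(g, a, b) .g_add(g, list(name = .g_name(g, "a"), op = "add",
                                             inputs = c(a, b)))
# elementwise product; the second input may have a single channel, which is
# broadcast across the channels of the first (attention gating)
g_mul <- function(g, a, b) .g_add(g, list(name = .g_name(g, "m"), op = "mul",
                                          inputs = c(a, b)))

.init_params <- function(g, seed) {
  .with_seed(seed, {
    params <- list()
    for (nm in names(g$param_shapes)) {
      shp <- g$param_shapes[[nm]]
      if (length(shp) == 2L) {
        fan_in <- shp[1]
        params[[nm]] <- matrix(stats::rnorm(prod(shp), sd = sqrt(2 / fan_in)),
                               shp[1], shp[2])
      } else if (startsWith(nm, "G_")) {
        params[[nm]] <- rep(1, shp)    # batch-norm scale
      } else {
        params[[nm]] <- rep(0, shp)
      }
    }
    params
  })
}

# channel axis is 4 in both layouts; b may have one channel (broadcast)
.bcast_mul <- function(a, b) {
  if (dim(b)[4] == dim(a)[4]) return(a * b)
  stopifnot(dim(b)[4] == 1L)
  a * array(b[, , , rep(1L, dim(a)[4]), drop = FALSE], dim(a))
}

# Batch-norm kernel: statistics over all non-channel axes. In training mode
# batch statistics are used and running buffers updated (momentum 0.1);
# otherwise the stored running statistics apply.
.bn_fwd <- function(x, gamma, beta, node, train, buffers) {
  d <- dim(x)
  nc <- d[4]
  eps <- 1e-5
  has_stats <- !is.null(buffers) && !is.null(buffers[[node]])
  if (train || !has_stats) {
    st <- cpp_bn_stats(x, nc)
    mu <- st$mean; var <- pmax(st$var, 0)
    if (train && !is.null(buffers)) {
      prev <- if (has_stats) buffers[[node]] else list(mean = mu, var = var)
      buffers[[node]] <- list(mean = 0.9 * prev$mean + 0.1 * mu,
                              var = 0.9 * prev$var + 0.1 * var)
    }
  } else {
    st <- buffers[[node]]
    mu <- st$mean; var <- st$var
  }
  invstd <- 1 / sqrt(var + eps)
  r <- cpp_bn_apply(x, gamma, beta, mu, invstd)
  list(out = r$out, xhat = r$xhat, invstd = invstd, d = d)
}

.bn_bwd <- function(dout, gamma, cache) {
  cpp_bn_bwd(dout, cache$xhat, gamma, cache$invstd)
}

# Forward pass; returns values (per node) and op caches for backward.
# `buffers` is an environment holding batch-norm running statistics; `train`
# selects batch statistics (and updates the buffers).
.forward <- function(g, params, x, want_cache = TRUE, train = FALSE,
                     buffers = NULL) {
  rank <- g$rank
  vals <- new.env(parent = emptyenv())
  caches <- if (want_cache) new.env(parent = emptyenv()) else NULL
  for (node in g$nodes) {
    v <- switch(node$op,
      input = x,
      conv = {
        r <- .conv_fwd(get(node$inputs, vals), params[[node$W]],
                       params[[node$b]], node$k, node$stride, rank)
        if (want_cache) assign(node$name, r$info, caches)
        r$out
      },
      upconv = {
        r <- .upconv_fwd(get(node$inputs, vals), params[[node$W]],
                         params[[node$b]], rank)
        if (want_cache) assign(node$name, r[c("xm", "d")], caches)
        r$out
      },
      bn = {
        r <- .bn_fwd(get(node$inputs, vals), params[[node$G]],
                     params[[node$B]], node$name, train, buffers)
        if (want_cache) assign(node$name, r[c("xhat", "invstd", "d")], caches)
        r$out
      },
      relu = pmax(get(node$inputs, vals), 0),
      sigmoid = 1 / (1 + exp(-get(node$inputs, vals))),
      maxpool = {
        r <- .maxpool_fwd(get(node$inputs, vals), rank)
        if (want_cache) assign(node$name, r[c("cands", "idx", "d", "out")], caches)
        r$out
      },
      concat = {
        r <- .concat_fwd(lapply(node$inputs, get, envir = vals))
        if (want_cache) assign(node$name, r$cs, caches)
        r$out
      },
      add = get(node$inputs[1], vals) + get(node$inputs[2], vals),
      mul = .bcast_mul(get(node$inputs[1], vals), get(node$inputs[2], vals)),
      stop("unknown op ", node$op))
    assign(node$name, v, vals)
  }
  list(out = get(g$nodes[[length(g$nodes)]]$name, vals), vals = vals,
       caches = caches)
}

# Reverse-mode pass: dOut is the loss gradient at the final node. Returns
# parameter gradients (named like params).
.backward <- function(g, params, fw, dOut) {
  rank <- g$rank
  vals <- fw$vals; caches <- fw$caches
  grads <- new.env(parent = emptyenv())
  pgrads <- list()
  nodes <- g$nodes
  assign(nodes[[length(nodes)]]$name, dOut, grads)
  acc <- function(nm, g_) {
    if (exists(nm, grads, inherits = FALSE))
      assign(nm, get(nm, grads) + g_, grads)
    else assign(nm, g_, grads)
  }
  for (node in rev(nodes)) {
    if (node$op == "input") next
    if (!exists(node$name, grads, inherits = FALSE)) next  # dead branch
    d <- get(node$name, grads)
    switch(node$op,
      conv = {
        # the gradient w.r.t. the network input is never used
        need_dx <- !identical(nodes[[node$inputs]]$op, "input")
        r <- .conv_bwd(d, params[[node$W]], get(node$name, caches), rank,
                       need_dx = need_dx || rank == 3L)
        pgrads[[node$W]] <- (pgrads[[node$W]] %||% 0) + r$dW
        pgrads[[node$b]] <- (pgrads[[node$b]] %||% 0) + r$db
        if (need_dx) acc(node$inputs, r$dx)
      },
      upconv = {
        r <- .upconv_bwd(d, params[[node$W]], get(node$name, caches), rank)
        pgrads[[node$W]] <- (pgrads[[node$W]] %||% 0) + r$dW
        pgrads[[node$b]] <- (pgrads[[node$b]] %||% 0) + r$db
        acc(node$inputs, r$dx)
      },
      bn = {
        r <- .bn_bwd(d, params[[node$G]], get(node$name, caches))
        pgrads[[node$G]] <- (pgrads[[node$G]] %||% 0) + r$dgamma
        pgrads[[node$B]] <- (pgrads[[node$B]] %||% 0) + r$dbeta
        acc(node$inputs, r$dx)
      },
      relu = acc(node$inputs, d * (get(node$inputs, vals) > 0)),
      sigmoid = {
        y <- get(node$name, vals)
        acc(node$inputs, d * y * (1 - y))
      },
      maxpool = acc(node$inputs, .maxpool_bwd(d, get(node$name, caches), rank)),
      concat = {
        parts <- .concat_bwd(d, get(node$name, caches))
        for (i in seq_along(node$inputs)) acc(node$inputs[i], parts[[i]])
      },
      add = {
        acc(node$inputs[1], d)
        acc(node$inputs[2], d)
      },
      mul = {
        a <- get(node$inputs[1], vals); b <- get(node$inputs[2], vals)
        acc(node$inputs[1], .bcast_mul(d, b))
        db_full <- d * a
        if (dim(b)[4] == 1L && dim(a)[4] > 1L) {
          # reduce the broadcast channel axis back to width 1
          db_red <- apply(db_full, 1:3, sum)
          dimb <- dim(a); dimb[4] <- 1L
          acc(node$inputs[2], array(db_red, dimb))
        } else acc(node$inputs[2], db_full)
      },
      stop("unknown op ", node$op))
  }
  pgrads
}

`%||%` <- function(a, b) if (is.null(a)) b else a
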