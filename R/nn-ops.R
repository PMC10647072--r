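# Tensor primitives for the compact CNN engine.
#
# No deep-learning framework is available in this stack, so convolutions are
# implemented in C++ as im2col gathers fused with BLAS GEMMs (src/conv_ops.cpp)
# plus hand-written backward passes. Layouts (column-major):
#   2D: [H, W, N, C]   (batch third, channels LAST)
#   3D: [D1, D2, D3, C]  (batch fixed at 1, matching volumetric training)
# so the channel axis is always axis 4 and GEMM outputs land directly in the
# tensor layout without transposition. Weights of a k-convolution are a
# (k^rank * Cin) x Cout matrix, rows ordered offset-major / channel-minor.

.conv_fwd <- function(x, W, b, k, stride, rank) {
  pad <- if (k > 1L) (k - 1L) %/% 2L else 0L
  d <- dim(x)
  r <- if (rank == 2L) cpp_conv2d_fwd(x, d, W, b, k, stride, pad)
       else cpp_conv3d_fwd(x, d, W, b, k, stride, pad)
  list(out = r$out, info = list(col = r$col, dims = d, k = k, stride = stride,
                                pad = pad))
}

.conv_bwd <- function(dout, W, info, rank, need_dx = TRUE) {
  r <- if (rank == 2L)
    cpp_conv2d_bwd(dout, info$col, info$dims, W, info$k, info$stride, info$pad,
                   need_dx)
  else
    cpp_conv3d_bwd(dout, info$col, info$dims, W, info$k, info$stride, info$pad)
  list(dx = r$dx, dW = r$dW, db = r$db)
}

# Transposed convolution, kernel 2, stride 2 (exact spatial doubling).
# W: Cin x (2^rank * Cout), column block o holds the weights for offset o.
.upconv_fwd <- function(x, W, b, rank) {
  d <- dim(x)
  cin <- d[4]
  xm <- matrix(x, ncol = cin)
  y <- xm %*% W
  cout <- length(b)
  if (rank == 2L) {
    out <- array(0, c(2L * d[1], 2L * d[2], d[3], cout))
    o <- 0L
    for (bj in 1:2) for (bi in 1:2) {
      out[seq(bi, 2L * d[1], 2L), seq(bj, 2L * d[2], 2L), , ] <-
        array(y[, o * cout + seq_len(cout)], c(d[1], d[2], d[3], cout))
      o <- o + 1L
    }
    out <- out + rep(b, each = 4L * d[1] * d[2] * d[3])
  } else {
    out <- array(0, c(2L * d[1:3], cout))
    o <- 0L
    for (bk in 1:2) for (bj in 1:2) for (bi in 1:2) {
      out[seq(bi, 2L * d[1], 2L), seq(bj, 2L * d[2], 2L),
          seq(bk, 2L * d[3], 2L), ] <- array(y[, o * cout + seq_len(cout)],
                                             c(d[1:3], cout))
      o <- o + 1L
    }
    out <- out + rep(b, each = 8L * prod(d[1:3]))
  }
  list(out = out, xm = xm, d = d)
}

.upconv_bwd <- function(dout, W, cache, rank) {
  d <- cache$d
  cout <- dim(dout)[4]
  n_off <- 2L^rank
  dy <- matrix(0, prod(d[1:3]), n_off * cout)
  o <- 0L
  if (rank == 2L) {
    for (bj in 1:2) for (bi in 1:2) {
      dy[, o * cout + seq_len(cout)] <-
        dout[seq(bi, 2L * d[1], 2L), seq(bj, 2L * d[2], 2L), , , drop = FALSE]
      o <- o + 1L
    }
  } else {
    for (bk in 1:2) for (bj in 1:2) for (bi in 1:2) {
      dy[, o * cout + seq_len(cout)] <-
        dout[seq(bi, 2L * d[1], 2L), seq(bj, 2L * d[2], 2L),
             seq(bk, 2L * d[3], 2L), , drop = FALSE]
      o <- o + 1L
    }
  }
  db <- colSums(matrix(dout, ncol = cout))
  dxm <- tcrossprod(dy, W)
  list(dx = array(dxm, d), dW = crossprod(cache$xm, dy), db = db)
}

# 2x max pooling over the spatial axes (extents must be even). Ties break
# toward the earliest window position, deterministically.
.maxpool_fwd <- function(x, rank) {
  d <- dim(x)
  if (rank == 2L) {
    idx <- list(c(1, 1), c(2, 1), c(1, 2), c(2, 2))
    cands <- lapply(idx, function(ij)
      x[seq(ij[1], d[1], 2L), seq(ij[2], d[2], 2L), , , drop = FALSE])
  } else {
    grid <- expand.grid(1:2, 1:2, 1:2)
    cands <- lapply(seq_len(nrow(grid)), function(r)
      x[seq(grid[r, 1], d[1], 2L), seq(grid[r, 2], d[2], 2L),
        seq(grid[r, 3], d[3], 2L), , drop = FALSE])
    idx <- lapply(seq_len(nrow(grid)), function(r) as.integer(grid[r, ]))
  }
  out <- Reduce(pmax, cands)
  list(out = out, cands = cands, idx = idx, d = d)
}

.maxpool_bwd <- function(dout, cache, rank) {
  dx <- array(0, cache$d)
  taken <- array(FALSE, dim(dout))
  for (i in seq_along(cache$cands)) {
    hit <- (cache$cands[[i]] == cache$out) & !taken
    taken <- taken | hit
    g <- dout * hit
    ij <- cache$idx[[i]]
    if (rank == 2L) {
      dx[seq(ij[1], cache$d[1], 2L), seq(ij[2], cache$d[2], 2L), , ] <- g
    } else {
      dx[seq(ij[1], cache$d[1], 2L), seq(ij[2], cache$d[2], 2L),
         seq(ij[3], cache$d[3], 2L), ] <- g
    }
  }
  dx
}

# channel axis is 4 in both layouts
.concat_fwd <- function(xs) {
  d <- dim(xs[[1]])
  cs <- vapply(xs, function(x) dim(x)[4], integer(1))
  dd <- d; dd[4] <- sum(cs)
  out <- array(0, dd)
  at <- 0L
  for (x in xs) {
    ci <- dim(x)[4]
    out[, , , at + seq_len(ci)] <- x
    at <- at + ci
  }
  list(out = out, cs = cs)
}

.concat_bwd <- function(dout, cs) {
  at <- 0L
  lapply(cs, function(ci) {
    g <- dout[, , , at + seq_len(ci), drop = FALSE]
    at <<- at + ci
    g
  })
}
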