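# Low-level 3D network operations.
#
# Volumes are carried as (V x C) matrices (V = prod(dims), R column-major
# voxel order) so convolutions reduce to gather + BLAS matrix products.
# Spatial index maps depend only on the grid shape and are memoized.

.nn_index_cache <- new.env(parent = emptyenv())

.grid_key <- function(dims, tag) paste(tag, paste(dims, collapse = "x"))

# Neighbor indices for a 3x3x3 convolution with zero padding 1:
# idx (V x 27) linear indices into the padded volume; interior: indices of
# the unpadded voxels inside the padded volume.
.conv_indices <- function(dims) {
  key <- .grid_key(dims, "conv")
  hit <- .nn_index_cache[[key]]
  if (!is.null(hit)) return(hit)
  d1 <- dims[1]; d2 <- dims[2]; d3 <- dims[3]
  p1 <- d1 + 2L; p2 <- d2 + 2L
  i <- rep(seq_len(d1) - 1L, times = d2 * d3)
  j <- rep(rep(seq_len(d2) - 1L, each = d1), times = d3)
  k <- rep(seq_len(d3) - 1L, each = d1 * d2)
  v <- d1 * d2 * d3
  idx <- matrix(0L, v, 27L)
  col <- 1L
  for (o3 in 0:2) for (o2 in 0:2) for (o1 in 0:2) {
    idx[, col] <- (i + o1) + (j + o2) * p1 + (k + o3) * p1 * p2 + 1L
    col <- col + 1L
  }
  interior <- (i + 1L) + (j + 1L) * p1 + (k + 1L) * p1 * p2 + 1L
  out <- list(idx = idx, interior = interior, padded_len = p1 * p2 * (d3 + 2L))
  .nn_index_cache[[key]] <- out
  out
}

# 2x2x2 max-pool children: (Vout x 8) linear indices into the input volume.
.pool_indices <- function(dims) {
  key <- .grid_key(dims, "pool")
  hit <- .nn_index_cache[[key]]
  if (!is.null(hit)) return(hit)
  stopifnot(all(dims %% 2L == 0L))
  h <- dims %/% 2L
  i <- rep(seq_len(h[1]) - 1L, times = h[2] * h[3])
  j <- rep(rep(seq_len(h[2]) - 1L, each = h[1]), times = h[3])
  k <- rep(seq_len(h[3]) - 1L, each = h[1] * h[2])
  idx <- matrix(0L, h[1] * h[2] * h[3], 8L)
  col <- 1L
  for (o3 in 0:1) for (o2 in 0:1) for (o1 in 0:1) {
    idx[, col] <- (2L * i + o1) + (2L * j + o2) * dims[1] +
      (2L * k + o3) * dims[1] * dims[2] + 1L
    col <- col + 1L
  }
  out <- list(idx = idx, out_dims = h)
  .nn_index_cache[[key]] <- out
  out
}

# Transposed-conv 2x upsampling: for each of the 8 offsets, the output
# linear indices written from every input voxel.
.up_indices <- function(dims) {
  key <- .grid_key(dims, "up")
  hit <- .nn_index_cache[[key]]
  if (!is.null(hit)) return(hit)
  o_dims <- dims * 2L
  i <- rep(seq_len(dims[1]) - 1L, times = dims[2] * dims[3])
  j <- rep(rep(seq_len(dims[2]) - 1L, each = dims[1]), times = dims[3])
  k <- rep(seq_len(dims[3]) - 1L, each = dims[1] * dims[2])
  idx <- matrix(0L, prod(dims), 8L)
  col <- 1L
  for (o3 in 0:1) for (o2 in 0:1) for (o1 in 0:1) {
    idx[, col] <- (2L * i + o1) + (2L * j + o2) * o_dims[1] +
      (2L * k + o3) * o_dims[1] * o_dims[2] + 1L
    col <- col + 1L
  }
  out <- list(idx = idx, out_dims = o_dims)
  .nn_index_cache[[key]] <- out
  out
}

# im2col: (V x C) input -> (V x 27C) patch matrix, channel-major blocks
# (channel c occupies columns (c-1)*27 + 1..27). Gathers are vectorized
# over channels: one (V x C) gather per kernel offset.
.im2col <- function(x, dims) {
  ci <- .conv_indices(dims)
  v <- nrow(x); nc <- ncol(x)
  out <- matrix(0, v, 27L * nc)
  pad <- matrix(0, ci$padded_len, nc)
  pad[ci$interior, ] <- x
  cols0 <- (seq_len(nc) - 1L) * 27L
  for (k in 1:27) {
    out[, cols0 + k] <- pad[ci$idx[, k], ]
  }
  out
}

# Scatter-add of the im2col gradient back onto the (V x C) input grid.
# Within one kernel offset the target indices are distinct, so plain
# indexed addition is safe.
.col2im <- function(dcol, dims, nc) {
  ci <- .conv_indices(dims)
  pad <- matrix(0, ci$padded_len, nc)
  cols0 <- (seq_len(nc) - 1L) * 27L
  for (k in 1:27) {
    tgt <- ci$idx[, k]
    pad[tgt, ] <- pad[tgt, ] + dcol[, cols0 + k]
  }
  pad[ci$interior, , drop = FALSE]
}

nn_conv3_forward <- function(x, dims, W, b) {
  xcol <- .im2col(x, dims)
  y <- xcol %*% W
  y <- sweep(y, 2, b, "+")
  list(y = y, xcol = xcol)
}

nn_conv3_backward <- function(dy, cache, W, in_channels, dims) {
  dW <- crossprod(cache$xcol, dy)
  db <- colSums(dy)
  dx <- .col2im(dy %*% t(W), dims, in_channels)
  list(dx = dx, dW = dW, db = db)
}

nn_dropout_forward <- function(x, rate, active) {
  if (!active || rate <= 0) return(list(y = x, mask = NULL))
  mask <- matrix(stats::rbinom(length(x), 1L, 1 - rate), nrow(x), ncol(x)) /
    (1 - rate)
  list(y = x * mask, mask = mask)
}

nn_dropout_backward <- function(dy, cache) {
  if (is.null(cache$mask)) dy else dy * cache$mask
}

nn_instnorm_forward <- function(x, gamma, beta, eps = 1e-5) {
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sd <- sqrt(colMeans(xc^2) + eps)
  xhat <- sweep(xc, 2, sd, "/")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(y = y, xhat = xhat, sd = sd)
}

nn_instnorm_backward <- function(dy, cache, gamma) {
  v <- nrow(dy)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, gamma, "*")
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * cache$xhat)
  dx <- sweep(dxhat, 2, m1) - sweep(cache$xhat, 2, m2, "*")
  dx <- sweep(dx, 2, cache$sd, "/")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

nn_leaky_forward <- function(x, slope) {
  list(y = ifelse(x > 0, x, slope * x), pos = x > 0)
}

nn_leaky_backward <- function(dy, cache, slope) {
  dy * ifelse(cache$pos, 1, slope)
}

nn_maxpool_forward <- function(x, dims) {
  pi_ <- .pool_indices(dims)
  vout <- nrow(pi_$idx); nc <- ncol(x)
  y <- matrix(0, vout, nc)
  amax <- matrix(0L, vout, nc)
  for (c in seq_len(nc)) {
    m <- matrix(x[pi_$idx, c], vout, 8L)
    a <- max.col(m, ties.method = "first")
    amax[, c] <- a
    y[, c] <- m[cbind(seq_len(vout), a)]
  }
  list(y = y, amax = amax, out_dims = pi_$out_dims, in_len = nrow(x))
}

nn_maxpool_backward <- function(dy, cache, dims) {
  pi_ <- .pool_indices(dims)
  vout <- nrow(dy); nc <- ncol(dy)
  dx <- matrix(0, cache$in_len, nc)
  for (c in seq_len(nc)) {
    src <- pi_$idx[cbind(seq_len(vout), cache$amax[, c])]
    dx[src, c] <- dy[, c]  # child sets of distinct outputs are disjoint
  }
  dx
}

# Transposed convolution, kernel 2^3, stride 2: one weight matrix per
# output offset. W: list of 8 (Cin x Cout) matrices; b: length Cout.
nn_upconv_forward <- function(x, dims, W, b) {
  ui <- .up_indices(dims)
  vout <- prod(ui$out_dims); nc_out <- ncol(W[[1]])
  y <- matrix(0, vout, nc_out)
  for (k in 1:8) y[ui$idx[, k], ] <- x %*% W[[k]]
  y <- sweep(y, 2, b, "+")
  list(y = y, out_dims = ui$out_dims)
}

nn_upconv_backward <- function(dy, x, dims, W) {
  ui <- .up_indices(dims)
  dW <- vector("list", 8L)
  dx <- matrix(0, nrow(x), ncol(x))
  for (k in 1:8) {
    dyk <- dy[ui$idx[, k], , drop = FALSE]
    dW[[k]] <- crossprod(x, dyk)
    dx <- dx + dyk %*% t(W[[k]])
  }
  list(dx = dx, dW = dW, db = colSums(dy))
}

nn_sigmoid <- function(z) 1 / (1 + exp(-z))

# He-uniform initializer: U(+-sqrt(6 / fan_in)).
he_uniform <- function(n_row, n_col, fan_in) {
  lim <- sqrt(6 / fan_in)
  matrix(stats::runif(n_row * n_col, -lim, lim), n_row, n_col)
}
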