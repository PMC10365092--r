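#' 3D U-Net model configuration
#'
#' Encoder-decoder segmentation network: `depth` downsampling blocks, each
#' 2 x (convolution, dropout, instance norm, leaky rectifier) followed by
#' 2x2x2 max pooling; a bottleneck block; a mirrored decoder with transposed
#' convolution upsampling and skip connections; and a per-class logistic
#' output head. Dropout is placed in the encoder blocks only, so enabling it
#' at inference yields Monte-Carlo (test-time dropout) predictions. Output
#' classes are independent (multi-label): tracts overlap spatially, so no
#' softmax is used.
#'
#' @param in_channels Input channels (15 SH coefficients for lmax = 4).
#' @param out_channels Number of tract classes.
#' @param depth Number of down/up-sampling blocks; patch sides must be
#'   divisible by `2^depth`. The full-scale profile uses 4; the desk-scale
#'   test profile uses 2.
#' @param base_filters Filters in the first encoder block (doubled per
#'   level).
#' @param dropout_rate Encoder dropout rate in [0, 1); 0.25 in the
#'   full-scale protocol.
#' @param negative_slope Leaky-rectifier slope for negative inputs.
#' @param head_bias Initial bias of the output (logit) layer. Tract
#'   foreground is sparse (a percent or less of brain voxels), so a
#'   negative initial bias starts the network at a probability near the
#'   foreground prevalence instead of 0.5; on short desk-scale budgets this
#'   frees the optimization from first spending many epochs suppressing the
#'   background. 0 reproduces the plain initialization.
#' @return Object of class `unet_config`.
#' @export
unet_config <- function(in_channels = 15, out_channels = 3, depth = 2,
                        base_filters = 8, dropout_rate = 0.25,
                        negative_slope = 0.01, head_bias = 0) {
  stopifnot(dropout_rate >= 0, dropout_rate < 1, depth >= 1, base_filters >= 1)
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 dropout_rate = dropout_rate,
                 negative_slope = negative_slope,
                 head_bias = head_bias),
            class = "unet_config")
}

.filters_at <- function(cfg, level) cfg$base_filters * 2L^(level - 1L)

.init_conv_unit <- function(cin, cout) {
  list(W = he_uniform(27L * cin, cout, fan_in = 27 * cin),
       b = numeric(cout), gamma = rep(1, cout), beta = numeric(cout))
}

#' Build and initialize a 3D U-Net
#'
#' Weights are drawn with the He-uniform scheme from a seeded stream, so the
#' same seed always yields the same initial parameters.
#'
#' @param config A [unet_config()].
#' @param seed Integer seed for the initializer.
#' @return Object of class `unet3d_model` (config + parameter list).
#' @export
build_model <- function(config, seed = 1) {
  set.seed(seed)
  p <- list()
  for (l in seq_len(config$depth)) {
    cin <- if (l == 1L) config$in_channels else .filters_at(config, l - 1L)
    cout <- .filters_at(config, l)
    p[[paste0("enc", l, "_u1")]] <- .init_conv_unit(cin, cout)
    p[[paste0("enc", l, "_u2")]] <- .init_conv_unit(cout, cout)
  }
  cb_in <- .filters_at(config, config$depth)
  cb <- .filters_at(config, config$depth + 1L)
  p$bot_u1 <- .init_conv_unit(cb_in, cb)
  p$bot_u2 <- .init_conv_unit(cb, cb)
  for (l in seq(config$depth, 1L)) {
    cin_up <- if (l == config$depth) cb else .filters_at(config, l + 1L)
    cout <- .filters_at(config, l)
    p[[paste0("up", l)]] <- list(
      W = lapply(1:8, function(k) he_uniform(cin_up, cout, fan_in = cin_up)),
      b = numeric(cout))
    p[[paste0("dec", l, "_u1")]] <- .init_conv_unit(2L * cout, cout)
    p[[paste0("dec", l, "_u2")]] <- .init_conv_unit(cout, cout)
  }
  hb <- if (is.null(config$head_bias)) 0 else config$head_bias
  p$out <- list(W = he_uniform(config$base_filters, config$out_channels,
                               fan_in = config$base_filters),
                b = rep(hb, config$out_channels))
  structure(list(config = config, params = p, seed = seed),
            class = "unet3d_model")
}

#' @export
print.unet3d_model <- function(x, ...) {
  n_par <- sum(vapply(rapply(x$params, length, how = "unlist"),
                      identity, numeric(1)))
  cat(sprintf(
    "unet3d_model: depth %d, %d -> %d channels, base %d, dropout %.2f (%d parameters)\n",
    x$config$depth, x$config$in_channels, x$config$out_channels,
    x$config$base_filters, x$config$dropout_rate, n_par))
  invisible(x)
}

.cu_forward <- function(unit, x, dims, rate, dropout_active, slope) {
  cv <- nn_conv3_forward(x, dims, unit$W, unit$b)
  dp <- nn_dropout_forward(cv$y, rate, dropout_active)
  ins <- nn_instnorm_forward(dp$y, unit$gamma, unit$beta)
  lr <- nn_leaky_forward(ins$y, slope)
  list(y = lr$y,
       cache = list(cv = cv, dp = dp, ins = ins, lr = lr,
                    cin = ncol(x), dims = dims))
}

.cu_backward <- function(unit, cache, dy, slope) {
  dy <- nn_leaky_backward(dy, cache$lr, slope)
  ib <- nn_instnorm_backward(dy, cache$ins, unit$gamma)
  dy <- nn_dropout_backward(ib$dx, cache$dp)
  cb <- nn_conv3_backward(dy, cache$cv, unit$W, cache$cin, cache$dims)
  list(dx = cb$dx,
       grads = list(W = cb$dW, b = cb$db, gamma = ib$dgamma, beta = ib$dbeta))
}

# Core forward pass on a (V x C) matrix over grid `dims`.
# Returns logits (V x N) and, when requested, the caches for backward.
.unet_forward_mat <- function(model, x, dims, dropout_active = FALSE,
                              want_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  if (ncol(x) != cfg$in_channels) {
    stop("input has ", ncol(x), " channels; model expects ", cfg$in_channels)
  }
  if (any(dims %% 2L^cfg$depth != 0L)) {
    stop("patch side ", paste(dims, collapse = "x"),
         " not divisible by 2^depth = ", 2L^cfg$depth)
  }
  rate <- cfg$dropout_rate
  slope <- cfg$negative_slope
  caches <- list()
  skips <- list()
  cur <- x
  cur_dims <- dims
  for (l in seq_len(cfg$depth)) {
    u1 <- .cu_forward(p[[paste0("enc", l, "_u1")]], cur, cur_dims, rate,
                      dropout_active, slope)
    u2 <- .cu_forward(p[[paste0("enc", l, "_u2")]], u1$y, cur_dims, rate,
                      dropout_active, slope)
    skips[[l]] <- u2$y
    pl <- nn_maxpool_forward(u2$y, cur_dims)
    if (want_cache) caches[[paste0("enc", l)]] <-
      list(u1 = u1$cache, u2 = u2$cache, pool = pl, dims = cur_dims)
    cur <- pl$y
    cur_dims <- pl$out_dims
  }
  b1 <- .cu_forward(p$bot_u1, cur, cur_dims, 0, FALSE, slope)
  b2 <- .cu_forward(p$bot_u2, b1$y, cur_dims, 0, FALSE, slope)
  if (want_cache) caches$bot <- list(u1 = b1$cache, u2 = b2$cache,
                                     dims = cur_dims)
  cur <- b2$y
  for (l in seq(cfg$depth, 1L)) {
    up <- nn_upconv_forward(cur, cur_dims, p[[paste0("up", l)]]$W,
                            p[[paste0("up", l)]]$b)
    cat_x <- cbind(up$y, skips[[l]])
    d_dims <- up$out_dims
    d1 <- .cu_forward(p[[paste0("dec", l, "_u1")]], cat_x, d_dims, 0, FALSE,
                      slope)
    d2 <- .cu_forward(p[[paste0("dec", l, "_u2")]], d1$y, d_dims, 0, FALSE,
                      slope)
    if (want_cache) caches[[paste0("dec", l)]] <-
      list(up_in = cur, up_in_dims = cur_dims, up_nc = ncol(up$y),
           u1 = d1$cache, u2 = d2$cache)
    cur <- d2$y
    cur_dims <- d_dims
  }
  logits <- sweep(cur %*% p$out$W, 2, p$out$b, "+")
  if (want_cache) caches$out_in <- cur
  list(logits = logits, caches = if (want_cache) caches else NULL,
       dims = cur_dims)
}

# Backward pass for gradients w.r.t. all parameters given d(loss)/d(logits).
.unet_backward_mat <- function(model, fwd, dlogits) {
  cfg <- model$config
  p <- model$params
  slope <- cfg$negative_slope
  g <- list()
  g$out <- list(W = crossprod(fwd$caches$out_in, dlogits),
                b = colSums(dlogits))
  dcur <- dlogits %*% t(p$out$W)
  dskips <- vector("list", cfg$depth)
  for (l in seq_len(cfg$depth)) {
    cc <- fwd$caches[[paste0("dec", l)]]
    b2 <- .cu_backward(p[[paste0("dec", l, "_u2")]], cc$u2, dcur, slope)
    b1 <- .cu_backward(p[[paste0("dec", l, "_u1")]], cc$u1, b2$dx, slope)
    g[[paste0("dec", l, "_u2")]] <- b2$grads
    g[[paste0("dec", l, "_u1")]] <- b1$grads
    dup <- b1$dx[, seq_len(cc$up_nc), drop = FALSE]
    dskips[[l]] <- b1$dx[, -seq_len(cc$up_nc), drop = FALSE]
    ub <- nn_upconv_backward(dup, cc$up_in, cc$up_in_dims,
                             p[[paste0("up", l)]]$W)
    g[[paste0("up", l)]] <- list(W = ub$dW, b = ub$db)
    dcur <- ub$dx
  }
  cb <- fwd$caches$bot
  b2 <- .cu_backward(p$bot_u2, cb$u2, dcur, slope)
  b1 <- .cu_backward(p$bot_u1, cb$u1, b2$dx, slope)
  g$bot_u2 <- b2$grads
  g$bot_u1 <- b1$grads
  dcur <- b1$dx
  for (l in seq(cfg$depth, 1L)) {
    cc <- fwd$caches[[paste0("enc", l)]]
    dpool <- nn_maxpool_backward(dcur, cc$pool, cc$dims)
    dpool <- dpool + dskips[[l]]
    b2 <- .cu_backward(p[[paste0("enc", l, "_u2")]], cc$u2, dpool, slope)
    b1 <- .cu_backward(p[[paste0("enc", l, "_u1")]], cc$u1, b2$dx, slope)
    g[[paste0("enc", l, "_u2")]] <- b2$grads
    g[[paste0("enc", l, "_u1")]] <- b1$grads
    dcur <- b1$dx
  }
  g
}

#' Forward pass of the segmentation network
#'
#' @param model A [build_model()] result.
#' @param patch 4D array (X, Y, Z, C) with C = `in_channels`; each spatial
#'   side must be divisible by `2^depth`.
#' @param dropout_active If TRUE, encoder dropout masks are sampled (from
#'   the current R random stream), making the pass stochastic -- the
#'   test-time-dropout mechanism. If FALSE the pass is deterministic.
#' @return 4D array (X, Y, Z, N) of per-class probabilities in (0, 1).
#' @export
unet_forward <- function(model, patch, dropout_active = FALSE) {
  dm <- dim(patch)
  stopifnot(length(dm) == 4L)
  x <- matrix(patch, prod(dm[1:3]), dm[4])
  out <- .unet_forward_mat(model, x, dm[1:3], dropout_active = dropout_active)
  array(nn_sigmoid(out$logits), c(dm[1:3], model$config$out_channels))
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the full parameter set, configuration and
#' initialization seed.
#'
#' @param model A `unet3d_model`.
#' @param path Destination file.
#' @return `save_checkpoint` returns the path invisibly; `load_checkpoint`
#'   returns the model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "unet3d_model"))
  model
}
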