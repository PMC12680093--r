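# Internal layer primitives with explicit forward/backward passes.
#
# Every layer is a plain list of parameter arrays plus static geometry; batch
# normalization additionally carries a `state` environment holding running
# statistics (reference semantics, so eval-mode forwards see the statistics
# accumulated during training without threading updated layers around).
#
# Forward functions return list(out, cache); backward functions take the
# upstream gradient plus the cache and return list(dx, grads) where `grads`
# mirrors the layer's trainable parameter names.

kaiming_sd <- function(fan_in) sqrt(2 / fan_in)

nn_conv3d <- function(in_channels, out_channels, kernel, stride = c(1L, 1L, 1L),
                      pad = NULL, bias = TRUE) {
  kernel <- rep(as.integer(kernel), length.out = 3L)
  stride <- rep(as.integer(stride), length.out = 3L)
  if (is.null(pad)) pad <- kernel %/% 2L
  pad <- rep(as.integer(pad), length.out = 3L)
  K <- in_channels * prod(kernel)
  w <- matrix(stats::rnorm(out_channels * K, sd = kaiming_sd(K)),
              nrow = out_channels)
  list(type = "conv3d", w = w,
       b = if (bias) numeric(out_channels) else NULL,
       in_channels = as.integer(in_channels),
       out_channels = as.integer(out_channels),
       kernel = kernel, stride = stride, pad = pad)
}

conv3d_fwd <- function(layer, x) {
  d <- dim(x)
  if (d[2] != layer$in_channels)
    stop("conv3d: input has ", d[2], " channels, layer expects ",
         layer$in_channels, call. = FALSE)
  b <- if (is.null(layer$b)) numeric(layer$out_channels) else layer$b
  out <- .conv3d_forward_cpp(x, as.integer(d), layer$w, b,
                             layer$kernel, layer$stride, layer$pad)
  list(out = out, cache = list(x = x))
}

conv3d_bwd <- function(layer, dout, cache, need_dx = TRUE) {
  x <- cache$x
  res <- .conv3d_backward_cpp(dout, x, as.integer(dim(x)), layer$w,
                              layer$kernel, layer$stride, layer$pad,
                              isTRUE(need_dx))
  grads <- list(w = res$dw)
  if (!is.null(layer$b)) grads$b <- res$db
  list(dx = res$dx, grads = grads)
}

# Batch normalization over (B, D, H, W) per channel; `mode = "instance"`
# normalizes per (sample, channel) instead, for batch-size-1 fine-tuning.
nn_bn3d <- function(channels, momentum = 0.2, eps = 1e-5) {
  state <- new.env(parent = emptyenv())
  state$mean <- numeric(channels)
  state$var <- rep(1, channels)
  list(type = "bn3d", gamma = rep(1, channels), beta = numeric(channels),
       channels = as.integer(channels), momentum = momentum, eps = eps,
       state = state)
}

bn3d_fwd <- function(layer, x, train = TRUE, mode = "batch") {
  d <- dim(x)
  B <- d[1]; C <- d[2]; M <- prod(d[3:5])
  R <- B * C
  g_bc <- rep(layer$gamma, each = B)
  b_bc <- rep(layer$beta, each = B)
  mu_c <- NULL; var_c <- NULL
  if (mode == "instance") {
    # true instance normalization: per-(sample, channel) statistics in both
    # training and eval mode (no running-statistics lag)
    st <- .row_stats_cpp(x, R)
    mu_bc <- st[1, ] / M
    var_bc <- pmax(st[2, ] / M - mu_bc^2, 0)
    mu_c <- colMeans(matrix(mu_bc, B, C))
    var_c <- colMeans(matrix(var_bc, B, C))
  } else if (train) {
    st <- .row_stats_cpp(x, R)
    mu_c <- colSums(matrix(st[1, ], B, C)) / (B * M)
    var_c <- pmax(colSums(matrix(st[2, ], B, C)) / (B * M) - mu_c^2, 0)
    mu_bc <- rep(mu_c, each = B)
    var_bc <- rep(var_c, each = B)
  } else {
    mu_bc <- rep(layer$state$mean, each = B)
    var_bc <- rep(layer$state$var, each = B)
  }
  inv_bc <- 1 / sqrt(var_bc + layer$eps)
  ap <- .bn_apply_cpp(x, mu_bc, inv_bc, g_bc, b_bc)
  y <- ap$y
  dim(y) <- d
  if (train) {
    m <- layer$momentum
    layer$state$mean <- (1 - m) * layer$state$mean + m * mu_c
    layer$state$var <- (1 - m) * layer$state$var + m * var_c
  }
  list(out = y,
       cache = list(xhat = ap$xhat, inv_bc = inv_bc, dims = d,
                    train = train, mode = mode, M = M))
}

bn3d_bwd <- function(layer, dout, cache) {
  d <- cache$dims
  B <- d[1]; C <- d[2]; M <- cache$M
  R <- B * C
  red <- .bn_reduce_cpp(dout, cache$xhat, R)  # rowSums(dm), rowSums(dm*xhat)
  dbeta <- colSums(matrix(red[1, ], B, C))
  dgamma <- colSums(matrix(red[2, ], B, C))
  g_bc <- rep(layer$gamma, each = B)
  if (cache$mode == "instance") {
    c1 <- g_bc * red[1, ] / M
    c2 <- g_bc * red[2, ] / M
  } else if (!cache$train) {
    c1 <- numeric(R)
    c2 <- numeric(R)
  } else {
    n_norm <- B * M
    c1 <- rep(layer$gamma * dbeta / n_norm, each = B)
    c2 <- rep(layer$gamma * dgamma / n_norm, each = B)
  }
  dx <- .bn_dx_cpp(dout, cache$xhat, g_bc, c1, c2, cache$inv_bc)
  dim(dx) <- d
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

relu_fwd <- function(x) {
  out <- .relu_fwd_cpp(x)
  dim(out) <- dim(x)
  list(out = out, cache = out)
}

relu_bwd <- function(dout, cache) {
  dx <- .relu_bwd_cpp(dout, cache)
  dim(dx) <- dim(dout)
  dx
}

nn_maxpool3d <- function(kernel, stride, pad) {
  list(type = "maxpool3d", kernel = rep(as.integer(kernel), length.out = 3L),
       stride = rep(as.integer(stride), length.out = 3L),
       pad = rep(as.integer(pad), length.out = 3L))
}

maxpool3d_fwd <- function(layer, x) {
  res <- .maxpool3d_forward_cpp(x, as.integer(dim(x)), layer$kernel,
                                layer$stride, layer$pad)
  list(out = res$out, cache = list(argmax = res$argmax, xlen = length(x),
                                   xdim = as.integer(dim(x))))
}

maxpool3d_bwd <- function(dout, cache) {
  .maxpool3d_backward_cpp(dout, cache$argmax, cache$xlen, cache$xdim)
}

nn_linear <- function(in_features, out_features, sd = NULL) {
  if (is.null(sd)) sd <- kaiming_sd(in_features)
  list(type = "linear",
       w = matrix(stats::rnorm(out_features * in_features, sd = sd),
                  nrow = out_features),
       b = numeric(out_features))
}

# x: (N x in) matrix of row vectors
linear_fwd <- function(layer, x) {
  out <- x %*% t(layer$w)
  out <- sweep(out, 2L, layer$b, "+")
  list(out = out, cache = list(x = x))
}

linear_bwd <- function(layer, dout, cache) {
  list(dx = dout %*% layer$w,
       grads = list(w = t(dout) %*% cache$x, b = colSums(dout)))
}

dropout_fwd <- function(x, p, train) {
  if (!train || p <= 0) return(list(out = x, cache = NULL))
  keep <- stats::runif(length(x)) >= p
  scale <- 1 / (1 - p)
  y <- x * (keep * scale)
  list(out = y, cache = list(keep = keep, scale = scale))
}

dropout_bwd <- function(dout, cache) {
  if (is.null(cache)) return(dout)
  dout * (cache$keep * cache$scale)
}

# Global average pool (B,C,D,H,W) -> (B,C)
gap_fwd <- function(x) {
  d <- dim(x)
  B <- d[1]; C <- d[2]; M <- prod(d[3:5])
  xm <- x
  dim(xm) <- c(B * C, M)
  out <- matrix(rowMeans(xm), B, C)
  list(out = out, cache = list(dims = d, M = M))
}

gap_bwd <- function(dout, cache) {
  d <- cache$dims
  dx <- array(rep(as.vector(dout) / cache$M, times = cache$M), dim = d)
  dx
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Softmax cross-entropy with integer labels in 0..(K-1); returns mean loss
# over the batch and the gradient w.r.t. the logits.
cross_entropy <- function(logits, labels) {
  B <- nrow(logits)
  m <- apply(logits, 1L, max)
  z <- exp(logits - m)
  p <- z / rowSums(z)
  idx <- cbind(seq_len(B), labels + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  dlogits <- dlogits / B
  list(loss = loss, dlogits = dlogits, probs = p)
}
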