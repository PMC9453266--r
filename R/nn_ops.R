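# Elementary differentiable layers: 3D convolution (compiled core), batch
# normalization, ReLU, global average pooling and the linear head. Each layer
# has a forward returning an optional cache and a matching backward.

#' 3D convolution
#'
#' Cross-correlation of a feature volume with a cubic kernel (spatial size 1
#' or 3), equal stride and zero-padding on every axis. Output spatial size per
#' axis is `floor((n + 2 pad - k) / stride) + 1`.
#'
#' @param x feature volume `(d1, d2, d3, in_ch, batch)`.
#' @param kernel array `(k, k, k, in_ch, out_ch)` with `k` 1 or 3.
#' @param bias optional length-`out_ch` vector.
#' @param stride,pad non-negative integers (shared by all spatial axes).
#' @return feature volume `(o1, o2, o3, out_ch, batch)`.
#' @export
conv3d <- function(x, kernel, bias = NULL, stride = 1L, pad = 0L) {
  check_feature_volume(x)
  kd <- dim(kernel)
  if (length(kd) != 5L) stop("kernel must be a rank-5 array (k,k,k,in,out)", call. = FALSE)
  if (kd[4] != fv_channels(x))
    stop(sprintf("kernel expects %d input channels, x has %d", kd[4], fv_channels(x)),
         call. = FALSE)
  conv3d_fwd_cpp(x, kernel, bias, as.integer(stride), as.integer(pad))
}

conv3d_backward <- function(x, kernel, dy, stride = 1L, pad = 0L) {
  conv3d_bwd_cpp(x, kernel, dy, as.integer(stride), as.integer(pad))
}

conv_out_dim <- function(n, k, stride, pad) (n + 2 * pad - k) %/% stride + 1

# ---- batch normalization ---------------------------------------------------

new_bn_params <- function(ch, eps = 1e-5) {
  list(gamma = rep(1, ch), beta = rep(0, ch),
       running_mean = rep(0, ch), running_var = rep(1, ch), eps = eps)
}

# Broadcast a per-channel vector over a feature volume's layout.
bcast_channel <- function(v, d) rep(rep(v, each = prod(d[1:3])), times = d[5])

# Batch normalization over (spatial, batch) per channel. In training mode the
# batch statistics are used (biased variance) and EMA-updated running
# statistics are returned in the cache; in eval mode the running statistics
# are applied as a fixed affine map.
bn_forward <- function(x, bn, training = FALSE, momentum = 0.1, want_cache = training) {
  d <- dim(x)
  S <- prod(d[1:3]); C <- d[4]; B <- d[5]
  if (C != length(bn$gamma)) stop("batch-norm channel mismatch", call. = FALSE)
  if (training) {
    xm <- matrix(aperm(array(x, c(S, C, B)), c(1, 3, 2)), S * B, C)
    mu <- .colMeans(xm, S * B, C)
    va <- .colMeans(xm * xm, S * B, C) - mu^2
    va[va < 0] <- 0
    bn$running_mean <- (1 - momentum) * bn$running_mean + momentum * mu
    bn$running_var  <- (1 - momentum) * bn$running_var  + momentum * va
  } else {
    mu <- bn$running_mean
    va <- bn$running_var
  }
  istd <- 1 / sqrt(va + bn$eps)
  sc <- bn$gamma * istd
  y <- x * bcast_channel(sc, d) + bcast_channel(bn$beta - sc * mu, d)
  cache <- NULL
  if (want_cache) {
    xhat <- (x - bcast_channel(mu, d)) * bcast_channel(istd, d)
    cache <- list(xhat = xhat, istd = istd, gamma = bn$gamma, training = training,
                  running_mean = bn$running_mean, running_var = bn$running_var)
  }
  list(y = y, cache = cache, bn = bn)
}

bn_backward <- function(dy, cache) {
  d <- dim(dy)
  S <- prod(d[1:3]); C <- d[4]; B <- d[5]
  m <- S * B
  xhat <- cache$xhat
  to_mat <- function(a) matrix(aperm(array(a, c(S, C, B)), c(1, 3, 2)), m, C)
  dym <- to_mat(dy)
  xhm <- to_mat(xhat)
  dgamma <- .colSums(dym * xhm, m, C)
  dbeta <- .colSums(dym, m, C)
  if (cache$training) {
    t1 <- dy - bcast_channel(dbeta / m, d) - xhat * bcast_channel(dgamma / m, d)
    dx <- t1 * bcast_channel(cache$gamma * cache$istd, d)
  } else {
    dx <- dy * bcast_channel(cache$gamma * cache$istd, d)
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- ReLU ------------------------------------------------------------------

relu_forward <- function(x, want_cache = TRUE) {
  y <- relu(x)
  list(y = y, cache = if (want_cache) (x > 0) else NULL)
}

relu_backward <- function(dy, mask) dy * mask

# ---- global average pooling ------------------------------------------------

# (d1,d2,d3,C,B) -> feature matrix (B x C)
gap_forward <- function(x) {
  d <- dim(x)
  S <- prod(d[1:3])
  f <- t(matrix(.colMeans(matrix(x, S, d[4] * d[5]), S, d[4] * d[5]), d[4], d[5]))
  list(y = f, spatial = d[1:3])
}

gap_backward <- function(df, spatial) {
  # df: (B x C) -> gradient spread uniformly over spatial positions
  S <- prod(spatial)
  B <- nrow(df); C <- ncol(df)
  array(rep(as.numeric(t(df)) / S, each = S), c(spatial, C, B))
}

# ---- linear head -----------------------------------------------------------

linear_forward <- function(f, W, b) {
  # f: (B x C), W: (C x K), b: K
  y <- f %*% W
  y <- sweep(y, 2, b, "+")
  list(y = y)
}

linear_backward <- function(df_out, f, W) {
  list(dx = df_out %*% t(W), dW = t(f) %*% df_out, db = .colSums(df_out, nrow(df_out), ncol(df_out)))
}
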