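# Non-local Context Spatial Attention (NCSA): query/key/value 1x1x1
# embeddings, a global-context extraction path (spatially softmaxed pooling of
# the key embedding, 1x1x1 -> LayerNorm -> 1x1x1 transform, average pooling),
# context-modulated pairwise affinity, and non-local aggregation with a
# zero-initialized residual output projection.

#' Create NCSA block parameters
#'
#' All projections are 1x1x1 convolutions acting on the channel dimension and
#' preserve the trunk channel count. `out_proj` starts at zero, so a freshly
#' created block is the identity map.
#'
#' @param ch trunk channel count.
#' @param mode which embeddings the pooled context vector modulates:
#'   `"key"` (default; only the key embedding, as in the affinity formula) or
#'   `"all"` (key, query and value).
#' @param affinity_norm normalization of the pairwise affinity:
#'   `"softmax"` rows (embedded-Gaussian convention, default) or `"mean"`
#'   (divide by the number of positions).
#' @return object of class `ncsa_params`.
#' @export
new_ncsa_params <- function(ch, mode = c("key", "all"),
                            affinity_norm = c("softmax", "mean")) {
  mode <- match.arg(mode)
  affinity_norm <- match.arg(affinity_norm)
  pj <- function() matrix(stats::rnorm(ch * ch, sd = sqrt(2 / ch)), ch, ch)
  structure(list(
    theta = list(W = pj(), b = rep(0, ch)),
    phi   = list(W = pj(), b = rep(0, ch)),
    delta = list(W = pj(), b = rep(0, ch)),
    ctx_reduce = list(W = matrix(stats::rnorm(ch, sd = sqrt(2 / ch)), ch, 1),
                      b = 0),
    ctx_transform = list(W1 = pj(), b1 = rep(0, ch),
                         ln_gamma = rep(1, ch), ln_beta = rep(0, ch),
                         W2 = pj(), b2 = rep(0, ch), ln_eps = 1e-5),
    out_proj = list(W = matrix(0, ch, ch), b = rep(0, ch)),
    embed_ch = ch, mode = mode, affinity_norm = affinity_norm
  ), class = "ncsa_params")
}

#' Spatial softmax weight field
#'
#' Softmax of a single-channel volume over all spatial positions (per batch
#' sample), computed with max-subtraction for stability; the weights of each
#' sample sum to one.
#'
#' @param g feature volume `(d1, d2, d3, 1, batch)`.
#' @return array of the same shape holding the weights.
#' @export
spatial_softmax_weights <- function(g) {
  check_feature_volume(g)
  if (fv_channels(g) != 1L)
    stop("spatial softmax expects a single-channel volume", call. = FALSE)
  d <- dim(g)
  N <- prod(d[1:3])
  m <- matrix(g, N, d[5])
  m <- exp(sweep(m, 2, apply(m, 2, max), "-"))
  m <- sweep(m, 2, colSums(m), "/")
  array(m, d)
}

#' Normalize a raw affinity matrix into attention rows
#'
#' Row-wise softmax (default) turns each query row into a probability vector
#' over positions; the `"mean"` convention divides by the number of positions
#' instead.
#'
#' @param raw numeric matrix `(N, N)` or array `(N, N, batch)`.
#' @param method `"softmax"` or `"mean"`.
#' @return same shape as `raw`.
#' @export
normalize_affinity <- function(raw, method = c("softmax", "mean")) {
  method <- match.arg(method)
  norm1 <- function(m) {
    if (method == "mean") return(m / ncol(m))
    e <- exp(m - apply(m, 1, max))
    e / rowSums(e)
  }
  if (length(dim(raw)) == 3L) {
    out <- raw
    for (b in seq_len(dim(raw)[3])) out[, , b] <- norm1(raw[, , b])
    out
  } else norm1(as.matrix(raw))
}

layernorm_vec <- function(u, lg, lb, eps) {
  mu <- mean(u)
  v <- mean((u - mu)^2)
  istd <- 1 / sqrt(v + eps)
  xh <- (u - mu) * istd
  list(h = lg * xh + lb, xh = xh, istd = istd)
}

# context vector for one sample's key embedding (N x C matrix)
ncsa_context_sample <- function(Ft, p, want_cache = FALSE) {
  ct <- p$ctx_transform
  G <- drop(Ft %*% p$ctx_reduce$W) + p$ctx_reduce$b
  if (!all(is.finite(G))) stop("non-finite context logits", call. = FALSE)
  Gs <- G - max(G)
  beta <- exp(Gs) / sum(exp(Gs))
  Gout <- drop(crossprod(Ft, beta))                  # per-channel weighted pooling
  u <- drop(Gout %*% ct$W1) + ct$b1
  ln <- layernorm_vec(u, ct$ln_gamma, ct$ln_beta, ct$ln_eps)
  Gpp <- drop(ln$h %*% ct$W2) + ct$b2                # G'_out; avg pool of a
  ctx <- Gpp                                         # (1,1,1) map is itself
  if (!want_cache) return(list(ctx = ctx))
  list(ctx = ctx, beta = beta, Gout = Gout, u = u, ln = ln, Gpp = Gpp)
}

#' Global context vector of a key embedding
#'
#' Reduces the embedding to one channel, softmaxes it spatially into pooling
#' weights, pools the embedding per channel, applies the
#' conv–LayerNorm–conv channel transform, and average-pools to a per-channel
#' context vector.
#'
#' @param f_theta feature volume `(d1, d2, d3, ch, batch)` with
#'   `p$embed_ch` channels.
#' @param p [new_ncsa_params()].
#' @return array `(1, 1, 1, ch, batch)`.
#' @export
global_context <- function(f_theta, p) {
  check_feature_volume(f_theta)
  C <- p$embed_ch
  if (fv_channels(f_theta) != C)
    stop(sprintf("context path expects %d channels, got %d", C, fv_channels(f_theta)),
         call. = FALSE)
  d <- dim(f_theta)
  N <- prod(d[1:3]); B <- d[5]
  out <- array(0, c(1, 1, 1, C, B))
  for (b in seq_len(B)) {
    Ft <- matrix(f_theta[, , , , b], N, C)
    out[1, 1, 1, , b] <- ncsa_context_sample(Ft, p)$ctx
  }
  out
}

#' NCSA block forward pass
#'
#' Computes the query/key/value embeddings, modulates the key embedding by
#' the pooled global context, forms the pairwise position affinity, normalizes
#' it into attention rows, aggregates the value embedding, and adds the
#' projected result back onto the trunk: `y = x + out_proj(F_att)`. Output
#' shape always equals input shape; with a zero `out_proj` the block is the
#' identity.
#'
#' @param x feature volume with `p$embed_ch` channels.
#' @param p [new_ncsa_params()].
#' @param want_cache keep intermediates for backpropagation.
#' @return list with `y` (and `cache` when requested).
#' @export
ncsa_forward <- function(x, p, want_cache = FALSE) {
  check_feature_volume(x)
  C <- p$embed_ch
  if (fv_channels(x) != C)
    stop(sprintf("NCSA expects %d channels, got %d", C, fv_channels(x)), call. = FALSE)
  d <- dim(x)
  N <- prod(d[1:3]); B <- d[5]
  y <- x
  caches <- if (want_cache) vector("list", B) else NULL
  all_mode <- identical(p$mode, "all")
  for (b in seq_len(B)) {
    X <- matrix(x[, , , , b], N, C)
    Ft <- sweep(X %*% p$theta$W, 2, p$theta$b, "+")
    Fp <- sweep(X %*% p$phi$W, 2, p$phi$b, "+")
    Fd <- sweep(X %*% p$delta$W, 2, p$delta$b, "+")
    cx <- ncsa_context_sample(Ft, p, want_cache)
    Gpp <- cx$ctx
    Ftm <- sweep(Ft, 2, Gpp, "*")
    Fpm <- if (all_mode) sweep(Fp, 2, Gpp, "*") else Fp
    Fdm <- if (all_mode) sweep(Fd, 2, Gpp, "*") else Fd
    Araw <- Fpm %*% t(Ftm)
    if (!all(is.finite(Araw))) stop("non-finite affinity", call. = FALSE)
    A <- normalize_affinity(Araw, p$affinity_norm)
    Fatt <- A %*% Fdm
    O <- sweep(Fatt %*% p$out_proj$W, 2, p$out_proj$b, "+")
    y[, , , , b] <- array(matrix(x[, , , , b], N, C) + O, d[1:4])
    if (want_cache)
      caches[[b]] <- list(X = X, Ft = Ft, Fp = Fp, Fd = Fd, cx = cx,
                          Ftm = Ftm, Fpm = Fpm, Fdm = Fdm, A = A, Fatt = Fatt)
  }
  list(y = y, cache = caches)
}

ncsa_backward <- function(dy, p, cache, x_dim) {
  C <- p$embed_ch
  N <- prod(x_dim[1:3]); B <- x_dim[5]
  all_mode <- identical(p$mode, "all")
  ct <- p$ctx_transform
  g0 <- function(a) a * 0
  grads <- list(theta = lapply(p$theta, g0), phi = lapply(p$phi, g0),
                delta = lapply(p$delta, g0),
                ctx_reduce = lapply(p$ctx_reduce, g0),
                ctx_transform = list(W1 = g0(ct$W1), b1 = g0(ct$b1),
                                     ln_gamma = g0(ct$ln_gamma),
                                     ln_beta = g0(ct$ln_beta),
                                     W2 = g0(ct$W2), b2 = g0(ct$b2)),
                out_proj = lapply(p$out_proj, g0))
  dx <- dy
  for (b in seq_len(B)) {
    cc <- cache[[b]]
    dY <- matrix(dy[, , , , b], N, C)
    # residual + output projection
    dFatt <- dY %*% t(p$out_proj$W)
    grads$out_proj$W <- grads$out_proj$W + t(cc$Fatt) %*% dY
    grads$out_proj$b <- grads$out_proj$b + colSums(dY)
    # aggregation
    dA <- dFatt %*% t(cc$Fdm)
    dFdm <- t(cc$A) %*% dFatt
    if (p$affinity_norm == "softmax") {
      s <- rowSums(dA * cc$A)
      dAraw <- (dA - s) * cc$A
    } else dAraw <- dA / N
    dFpm <- dAraw %*% cc$Ftm
    dFtm <- t(dAraw) %*% cc$Fpm
    Gpp <- cc$cx$ctx
    dFt <- sweep(dFtm, 2, Gpp, "*")
    dGpp <- colSums(dFtm * cc$Ft)
    if (all_mode) {
      dFp <- sweep(dFpm, 2, Gpp, "*")
      dFd <- sweep(dFdm, 2, Gpp, "*")
      dGpp <- dGpp + colSums(dFpm * cc$Fp) + colSums(dFdm * cc$Fd)
    } else {
      dFp <- dFpm
      dFd <- dFdm
    }
    # context transform backward (vectors over channels)
    h <- cc$cx$ln$h
    dh <- drop(dGpp %*% t(ct$W2))
    grads$ctx_transform$W2 <- grads$ctx_transform$W2 + outer(h, dGpp)
    grads$ctx_transform$b2 <- grads$ctx_transform$b2 + dGpp
    xh <- cc$cx$ln$xh
    grads$ctx_transform$ln_gamma <- grads$ctx_transform$ln_gamma + dh * xh
    grads$ctx_transform$ln_beta <- grads$ctx_transform$ln_beta + dh
    dxh <- dh * ct$ln_gamma
    du <- cc$cx$ln$istd * (dxh - mean(dxh) - xh * mean(dxh * xh))
    dGout <- drop(du %*% t(ct$W1))
    grads$ctx_transform$W1 <- grads$ctx_transform$W1 + outer(cc$cx$Gout, du)
    grads$ctx_transform$b1 <- grads$ctx_transform$b1 + du
    # pooled context backward
    beta <- cc$cx$beta
    dFt <- dFt + outer(beta, dGout)
    dbeta <- drop(cc$Ft %*% dGout)
    dG <- (dbeta - sum(dbeta * beta)) * beta
    dFt <- dFt + dG %*% t(p$ctx_reduce$W)
    grads$ctx_reduce$W <- grads$ctx_reduce$W + t(cc$Ft) %*% dG
    grads$ctx_reduce$b <- grads$ctx_reduce$b + sum(dG)
    # projections back to the trunk
    dX <- dFt %*% t(p$theta$W) + dFp %*% t(p$phi$W) + dFd %*% t(p$delta$W)
    grads$theta$W <- grads$theta$W + t(cc$X) %*% dFt
    grads$theta$b <- grads$theta$b + colSums(dFt)
    grads$phi$W <- grads$phi$W + t(cc$X) %*% dFp
    grads$phi$b <- grads$phi$b + colSums(dFp)
    grads$delta$W <- grads$delta$W + t(cc$X) %*% dFd
    grads$delta$b <- grads$delta$b + colSums(dFd)
    dx[, , , , b] <- as.numeric(dx[, , , , b]) + as.numeric(dX)
  }
  list(dx = dx, grads = grads)
}
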