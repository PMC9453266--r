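# Independent reference implementations used as oracles, plus random
# parameter builders. These deliberately use naive loops / direct formulas,
# not the package's vectorized code paths.

# direct triple-loop 3D cross-correlation
naive_conv3d <- function(x, w, bias = NULL, stride = 1, pad = 0) {
  d <- dim(x); kd <- dim(w); k <- kd[1]
  o <- (d[1:3] + 2 * pad - k) %/% stride + 1
  y <- array(0, c(o, kd[5], d[5]))
  for (b in seq_len(d[5])) for (co in seq_len(kd[5]))
    for (i in seq_len(o[1])) for (j in seq_len(o[2])) for (l in seq_len(o[3])) {
      acc <- 0
      for (ci in seq_len(d[4])) for (a in 1:k) for (bb in 1:k) for (cc in 1:k) {
        xi <- (i - 1) * stride - pad + a
        yj <- (j - 1) * stride - pad + bb
        zl <- (l - 1) * stride - pad + cc
        if (xi >= 1 && xi <= d[1] && yj >= 1 && yj <= d[2] && zl >= 1 && zl <= d[3])
          acc <- acc + x[xi, yj, zl, ci, b] * w[a, bb, cc, ci, co]
      }
      y[i, j, l, co, b] <- acc + if (is.null(bias)) 0 else bias[co]
    }
  y
}

# direct per-channel eval-mode batch norm
naive_bn_eval <- function(x, gamma, beta, mean, var, eps) {
  d <- dim(x)
  y <- x
  for (c in seq_len(d[4])) for (b in seq_len(d[5]))
    y[, , , c, b] <- gamma[c] * (x[, , , c, b] - mean[c]) / sqrt(var[c] + eps) + beta[c]
  y
}

# conv_bn branch with random (non-identity) BN statistics
random_conv_bn <- function(k, in_ch, out_ch, stride = 1L) {
  conv_bn(resrepanet:::kaiming_kernel(k, in_ch, out_ch),
          bn_gamma = runif(out_ch, 0.5, 1.5), bn_beta = rnorm(out_ch),
          bn_mean = rnorm(out_ch), bn_var = runif(out_ch, 0.2, 2),
          stride = stride)
}

random_rep_stage <- function(ch, with_identity = TRUE) {
  bid <- if (with_identity)
    list(gamma = runif(ch, 0.5, 1.5), beta = rnorm(ch), mean = rnorm(ch),
         var = runif(ch, 0.2, 2), eps = 1e-5)
  else NULL
  rep_branch_params(branch3 = random_conv_bn(3, ch, ch),
                    branch1 = random_conv_bn(1, ch, ch),
                    branch_id = bid)
}

rand_fv <- function(d1, d2, d3, ch, batch = 1L) {
  array(rnorm(d1 * d2 * d3 * ch * batch), c(d1, d2, d3, ch, batch))
}

# literal nested-loop NCSA reference: explicit loops over positions for the
# spatial softmax, weighted pooling, affinity and aggregation.
ncsa_reference <- function(x, p) {
  d <- dim(x)
  N <- prod(d[1:3]); C <- p$embed_ch; B <- d[5]
  ct <- p$ctx_transform
  y <- x
  for (b in seq_len(B)) {
    X <- matrix(x[, , , , b], N, C)
    proj <- function(pr) {
      out <- matrix(0, N, C)
      for (i in seq_len(N)) for (c in seq_len(C))
        out[i, c] <- sum(X[i, ] * pr$W[, c]) + pr$b[c]
      out
    }
    Ft <- proj(p$theta); Fp <- proj(p$phi); Fd <- proj(p$delta)
    G <- numeric(N)
    for (i in seq_len(N)) G[i] <- sum(Ft[i, ] * p$ctx_reduce$W[, 1]) + p$ctx_reduce$b
    beta <- numeric(N)
    for (i in seq_len(N)) beta[i] <- exp(G[i]) / sum(exp(G))
    Gout <- numeric(C)
    for (c in seq_len(C)) for (j in seq_len(N)) Gout[c] <- Gout[c] + beta[j] * Ft[j, c]
    u <- numeric(C)
    for (c in seq_len(C)) u[c] <- sum(Gout * ct$W1[, c]) + ct$b1[c]
    mu <- mean(u); v <- mean((u - mu)^2)
    h <- ct$ln_gamma * (u - mu) / sqrt(v + ct$ln_eps) + ct$ln_beta
    Gpp <- numeric(C)
    for (c in seq_len(C)) Gpp[c] <- sum(h * ct$W2[, c]) + ct$b2[c]
    # average pooling of the (1,1,1) context map is the identity
    mod <- function(M) {
      out <- M
      for (i in seq_len(N)) for (c in seq_len(C)) out[i, c] <- M[i, c] * Gpp[c]
      out
    }
    Ftm <- mod(Ft)
    Fpm <- if (identical(p$mode, "all")) mod(Fp) else Fp
    Fdm <- if (identical(p$mode, "all")) mod(Fd) else Fd
    A <- matrix(0, N, N)
    for (i in seq_len(N)) for (j in seq_len(N)) A[i, j] <- sum(Fpm[i, ] * Ftm[j, ])
    for (i in seq_len(N)) {
      if (identical(p$affinity_norm, "softmax")) {
        e <- exp(A[i, ] - max(A[i, ]))
        A[i, ] <- e / sum(e)
      } else A[i, ] <- A[i, ] / N
    }
    Fatt <- matrix(0, N, C)
    for (i in seq_len(N)) for (c in seq_len(C))
      Fatt[i, c] <- sum(A[i, ] * Fdm[, c])
    O <- matrix(0, N, C)
    for (i in seq_len(N)) for (c in seq_len(C))
      O[i, c] <- sum(Fatt[i, ] * p$out_proj$W[, c]) + p$out_proj$b[c]
    y[, , , , b] <- array(X + O, d[1:4])
  }
  y
}

# literal per-sample double loop over the density definition
brute_force_density <- function(norms, n_bins = 10L, eps_guard = 1e-6) {
  N <- length(norms)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  out <- numeric(N)
  for (n in seq_len(N)) {
    bin <- min(floor(norms[n] * n_bins) + 1, n_bins)
    lo <- edges[bin]; hi <- edges[bin + 1]
    count <- 0
    for (m in seq_len(N)) {
      bm <- min(floor(norms[m] * n_bins) + 1, n_bins)
      if (bm == bin) count <- count + 1
    }
    width <- max(min(hi, 1) - max(lo, 0), eps_guard)
    out[n] <- count / width
  }
  out
}
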