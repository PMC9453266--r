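# ResRep blocks: multi-branch training-time stages (3x3x3 conv-BN + 1x1x1
# conv-BN + optional identity-BN) and their exact algebraic fusion into a
# single 3x3x3 convolution for deployment.

#' Convolution + batch-norm branch parameters
#'
#' One branch of a multi-branch stage: a cubic convolution (spatial size 1 or
#' 3) followed by per-channel batch normalization.
#'
#' @param kernel array `(k, k, k, in_ch, out_ch)`, `k` in \{1, 3\}.
#' @param bn_gamma,bn_beta,bn_mean,bn_var per-output-channel BN parameters and
#'   running statistics (`bn_var` elementwise non-negative).
#' @param bn_eps positive stabilizer.
#' @param stride positive integer stride shared by all spatial axes.
#' @param pad zero-padding; defaults to 1 for 3x3x3 kernels and 0 for 1x1x1.
#' @return an object of class `conv_bn`.
#' @export
conv_bn <- function(kernel, bn_gamma = NULL, bn_beta = NULL, bn_mean = NULL,
                    bn_var = NULL, bn_eps = 1e-5, stride = 1L, pad = NULL) {
  kd <- dim(kernel)
  if (length(kd) != 5L || kd[1] != kd[2] || kd[1] != kd[3] || !(kd[1] %in% c(1L, 3L)))
    stop("kernel must be (k,k,k,in,out) with cubic spatial size 1 or 3", call. = FALSE)
  out_ch <- kd[5]
  bn_gamma <- bn_gamma %||% rep(1, out_ch)
  bn_beta  <- bn_beta  %||% rep(0, out_ch)
  bn_mean  <- bn_mean  %||% rep(0, out_ch)
  bn_var   <- bn_var   %||% rep(1, out_ch)
  if (length(bn_gamma) != out_ch || length(bn_beta) != out_ch ||
      length(bn_mean) != out_ch || length(bn_var) != out_ch)
    stop("BN vectors must have one entry per output channel", call. = FALSE)
  if (any(bn_var < 0)) stop("bn_var must be non-negative", call. = FALSE)
  if (bn_eps <= 0) stop("bn_eps must be positive", call. = FALSE)
  pad <- pad %||% (if (kd[1] == 3L) 1L else 0L)
  structure(list(kernel = kernel, bn_gamma = bn_gamma, bn_beta = bn_beta,
                 bn_mean = bn_mean, bn_var = bn_var, bn_eps = bn_eps,
                 stride = as.integer(stride), pad = as.integer(pad)),
            class = "conv_bn")
}

as_bn_list <- function(cb) {
  list(gamma = cb$bn_gamma, beta = cb$bn_beta, running_mean = cb$bn_mean,
       running_var = cb$bn_var, eps = cb$bn_eps)
}

#' Fold batch normalization into a convolution
#'
#' Absorbs the (eval-mode) BN affine map into the preceding convolution:
#' `W' = W * gamma / sqrt(var + eps)` per output channel and
#' `b' = beta - gamma * mean / sqrt(var + eps)`, so that
#' `conv(x; W') + b'` equals `bn(conv(x; W))` for every input.
#'
#' @param cb a [conv_bn()] branch.
#' @return list with `kernel` (same spatial size as `cb$kernel`), `bias`,
#'   `stride`, `pad`.
#' @export
fold_bn <- function(cb) {
  if (!inherits(cb, "conv_bn")) stop("fold_bn expects a conv_bn object", call. = FALSE)
  kd <- dim(cb$kernel)
  sc <- cb$bn_gamma / sqrt(cb$bn_var + cb$bn_eps)
  W <- cb$kernel * rep(sc, each = prod(kd[1:4]))
  dim(W) <- kd
  list(kernel = W, bias = cb$bn_beta - sc * cb$bn_mean,
       stride = cb$stride, pad = cb$pad)
}

#' Embed a 1x1x1 kernel at the center of a zero 3x3x3 kernel
#'
#' Zero-padding a point kernel to spatial size 3 leaves the convolution
#' unchanged once the padded kernel is applied with padding 1.
#'
#' @param kernel_1 array `(1, 1, 1, in_ch, out_ch)`.
#' @return array `(3, 3, 3, in_ch, out_ch)`.
#' @export
pad_1x1_to_3x3 <- function(kernel_1) {
  kd <- dim(kernel_1)
  if (length(kd) != 5L || any(kd[1:3] != 1L))
    stop("kernel_1 must have spatial size 1x1x1", call. = FALSE)
  out <- array(0, c(3, 3, 3, kd[4], kd[5]))
  out[2, 2, 2, , ] <- kernel_1[1, 1, 1, , ]
  out
}

#' Dirac 3x3x3 kernel realizing the identity map
#'
#' `conv(x; K, pad = 1)` returns `x` exactly; used to express the identity-BN
#' branch of a three-branch stage as a convolution before fusion.
#'
#' @param in_ch,out_ch channel counts; must be equal.
#' @return array `(3, 3, 3, in_ch, out_ch)`.
#' @export
identity_to_3x3 <- function(in_ch, out_ch) {
  if (in_ch != out_ch)
    stop("identity branch requires in_ch == out_ch", call. = FALSE)
  K <- array(0, c(3, 3, 3, in_ch, out_ch))
  for (c in seq_len(in_ch)) K[2, 2, 2, c, c] <- 1
  K
}

#' Multi-branch stage parameters
#'
#' A channel-preserving stage with a 3x3x3 conv-BN branch, a 1x1x1 conv-BN
#' branch, and (when input and output channels match and the stride is 1) an
#' optional identity-BN branch. The stage output is the elementwise sum of
#' branch outputs.
#'
#' @param branch3 [conv_bn()] with 3x3x3 kernel.
#' @param branch1 [conv_bn()] with 1x1x1 kernel.
#' @param branch_id optional identity-BN branch: list with `gamma`, `beta`,
#'   `mean`, `var`, `eps` (per-channel).
#' @return object of class `rep_branch_params`.
#' @export
rep_branch_params <- function(branch3, branch1, branch_id = NULL) {
  kd3 <- dim(branch3$kernel); kd1 <- dim(branch1$kernel)
  if (kd3[1] != 3L) stop("branch3 must have a 3x3x3 kernel", call. = FALSE)
  if (kd1[1] != 1L) stop("branch1 must have a 1x1x1 kernel", call. = FALSE)
  if (kd3[4] != kd1[4] || kd3[5] != kd1[5])
    stop("branch3 and branch1 must share channel counts", call. = FALSE)
  if (branch3$stride != branch1$stride)
    stop("branches must share the stride", call. = FALSE)
  if (!is.null(branch_id)) {
    if (kd3[4] != kd3[5] || branch3$stride != 1L)
      stop("identity branch requires in_ch == out_ch and stride 1", call. = FALSE)
    if (length(branch_id$gamma) != kd3[5])
      stop("identity-BN vectors must have one entry per channel", call. = FALSE)
  }
  structure(list(branch3 = branch3, branch1 = branch1, branch_id = branch_id,
                 in_ch = kd3[4], out_ch = kd3[5]),
            class = "rep_branch_params")
}

new_identity_bn <- function(ch, eps = 1e-5) {
  list(gamma = rep(1, ch), beta = rep(0, ch), mean = rep(0, ch),
       var = rep(1, ch), eps = eps)
}

# Random stage used by constructors and tests.
new_rep_stage <- function(in_ch, out_ch, with_identity = in_ch == out_ch) {
  rep_branch_params(
    branch3 = conv_bn(kaiming_kernel(3, in_ch, out_ch), stride = 1L),
    branch1 = conv_bn(kaiming_kernel(1, in_ch, out_ch), stride = 1L),
    branch_id = if (with_identity) new_identity_bn(out_ch) else NULL
  )
}

id_bn_as_conv_bn <- function(bid, ch) {
  conv_bn(identity_to_3x3(ch, ch), bn_gamma = bid$gamma, bn_beta = bid$beta,
          bn_mean = bid$mean, bn_var = bid$var, bn_eps = bid$eps,
          stride = 1L, pad = 1L)
}

#' Fuse a multi-branch stage into a single 3x3x3 convolution
#'
#' Exact structural re-parameterization: each branch's BN is folded into its
#' convolution (the identity branch first expressed as a Dirac kernel), the
#' 1x1x1 kernel is center-embedded into spatial size 3, and kernels and biases
#' are summed. The fused convolution reproduces the sum of branch outputs for
#' every input (eval-mode BN statistics).
#'
#' @param p a [rep_branch_params()] stage.
#' @return object of class `fused_kernel`: list with `kernel`
#'   `(3,3,3,in,out)`, `bias`, `stride`, `pad`.
#' @export
fuse_stage <- function(p) {
  if (!inherits(p, "rep_branch_params"))
    stop("fuse_stage expects rep_branch_params", call. = FALSE)
  f3 <- fold_bn(p$branch3)
  f1 <- fold_bn(p$branch1)
  K <- f3$kernel + pad_1x1_to_3x3(f1$kernel)
  b <- f3$bias + f1$bias
  if (!is.null(p$branch_id)) {
    fid <- fold_bn(id_bn_as_conv_bn(p$branch_id, p$out_ch))
    K <- K + fid$kernel
    b <- b + fid$bias
  }
  structure(list(kernel = K, bias = b, stride = p$branch3$stride, pad = 1L),
            class = "fused_kernel")
}

# ---- forwards --------------------------------------------------------------

conv_bn_forward <- function(x, cb, training = FALSE, want_cache = FALSE) {
  z <- conv3d(x, cb$kernel, NULL, cb$stride, cb$pad)
  b <- bn_forward(z, as_bn_list(cb), training = training, want_cache = want_cache)
  cb$bn_mean <- b$bn$running_mean
  cb$bn_var <- b$bn$running_var
  cache <- if (want_cache) list(x = x, bn = b$cache) else NULL
  list(y = b$y, cache = cache, params = cb)
}

conv_bn_backward <- function(dy, cb, cache) {
  bb <- bn_backward(dy, cache$bn)
  cv <- conv3d_backward(cache$x, cb$kernel, bb$dx, cb$stride, cb$pad)
  list(dx = cv$dx,
       grads = list(kernel = cv$dw, bn_gamma = bb$dgamma, bn_beta = bb$dbeta))
}

#' Multi-branch stage forward (training form)
#'
#' Sum of the branch outputs (pre-activation); the surrounding block applies
#' ReLU.
#' @param x feature volume; @param p stage parameters.
#' @param training use batch statistics in every BN.
#' @param want_cache keep intermediates for backpropagation.
#' @keywords internal
rep_stage_forward <- function(x, p, training = FALSE, want_cache = FALSE) {
  f3 <- conv_bn_forward(x, p$branch3, training, want_cache)
  f1 <- conv_bn_forward(x, p$branch1, training, want_cache)
  y <- f3$y + f1$y
  idc <- NULL
  if (!is.null(p$branch_id)) {
    bid <- p$branch_id
    bl <- list(gamma = bid$gamma, beta = bid$beta, running_mean = bid$mean,
               running_var = bid$var, eps = bid$eps)
    fb <- bn_forward(x, bl, training = training, want_cache = want_cache)
    y <- y + fb$y
    p$branch_id$mean <- fb$bn$running_mean
    p$branch_id$var <- fb$bn$running_var
    idc <- fb$cache
  }
  p$branch3 <- f3$params
  p$branch1 <- f1$params
  cache <- if (want_cache) list(b3 = f3$cache, b1 = f1$cache, bid = idc) else NULL
  list(y = y, cache = cache, params = p)
}

rep_stage_backward <- function(dy, p, cache) {
  g3 <- conv_bn_backward(dy, p$branch3, cache$b3)
  g1 <- conv_bn_backward(dy, p$branch1, cache$b1)
  dx <- g3$dx + g1$dx
  grads <- list(branch3 = g3$grads, branch1 = g1$grads)
  if (!is.null(p$branch_id)) {
    gb <- bn_backward(dy, cache$bid)
    dx <- dx + gb$dx
    grads$branch_id <- list(gamma = gb$dgamma, beta = gb$dbeta)
  }
  list(dx = dx, grads = grads)
}

#' Create a randomly initialized ResRep block
#'
#' A block is a stride-2 3x3x3 conv-BN stem performing the channel change,
#' followed by two channel-preserving multi-branch stages: a two-branch stage
#' (3x3x3 + 1x1x1) and a three-branch stage that adds an identity-BN branch.
#' Kernels are Kaiming-normal; BN starts as the identity map.
#'
#' @param in_ch,out_ch channel counts.
#' @return object of class `resrep_block`.
#' @export
new_resrep_block <- function(in_ch, out_ch) {
  structure(list(
    stem = conv_bn(kaiming_kernel(3, in_ch, out_ch), stride = 2L),
    stage_a = new_rep_stage(out_ch, out_ch, with_identity = FALSE),
    stage_b = new_rep_stage(out_ch, out_ch, with_identity = TRUE),
    in_ch = in_ch, out_ch = out_ch, deploy = FALSE
  ), class = "resrep_block")
}

#' ResRep block forward pass
#'
#' Training form: `X' = bn(conv3_stride2(X))`, then
#' `l1 = relu(conv3(X') + conv1(X'))`, then
#' `l1' = relu(conv3(l1) + conv1(l1) + bn(l1))`. The deploy form runs one
#' fused 3x3x3 convolution (+ bias) per stage instead of the branch sums.
#'
#' @param x feature volume with `block$in_ch` channels.
#' @param block a [new_resrep_block()] (train or deploy form).
#' @param training use batch statistics in BN layers.
#' @param want_cache keep intermediates for backpropagation.
#' @return list with `y` (and `cache`, `params` when requested).
#' @export
resrep_block_forward <- function(x, block, training = FALSE, want_cache = FALSE) {
  if (fv_channels(x) != block$in_ch)
    stop(sprintf("block expects %d input channels, got %d", block$in_ch, fv_channels(x)),
         call. = FALSE)
  if (isTRUE(block$deploy)) {
    xp <- conv3d(x, block$stem$kernel, block$stem$bias, block$stem$stride, block$stem$pad)
    a <- relu(conv3d(xp, block$stage_a$kernel, block$stage_a$bias, 1L, 1L))
    y <- relu(conv3d(a, block$stage_b$kernel, block$stage_b$bias, 1L, 1L))
    return(list(y = y, cache = NULL, params = block))
  }
  st <- conv_bn_forward(x, block$stem, training, want_cache)
  sa <- rep_stage_forward(st$y, block$stage_a, training, want_cache)
  ra <- relu_forward(sa$y, want_cache)
  sb <- rep_stage_forward(ra$y, block$stage_b, training, want_cache)
  rb <- relu_forward(sb$y, want_cache)
  block$stem <- st$params
  block$stage_a <- sa$params
  block$stage_b <- sb$params
  cache <- if (want_cache) {
    list(stem = st$cache, stage_a = sa$cache, ra = ra$cache,
         stage_b = sb$cache, rb = rb$cache)
  } else NULL
  list(y = rb$y, cache = cache, params = block)
}

resrep_block_backward <- function(dy, block, cache) {
  dy <- relu_backward(dy, cache$rb)
  gb <- rep_stage_backward(dy, block$stage_b, cache$stage_b)
  da <- relu_backward(gb$dx, cache$ra)
  ga <- rep_stage_backward(da, block$stage_a, cache$stage_a)
  gs <- conv_bn_backward(ga$dx, block$stem, cache$stem)
  list(dx = gs$dx,
       grads = list(stem = gs$grads, stage_a = ga$grads, stage_b = gb$grads))
}

#' Convert a ResRep block to its deploy form
#'
#' Folds the stem BN into the stem convolution and fuses each multi-branch
#' stage into a single 3x3x3 convolution + bias ([fuse_stage()]). The deploy
#' form contains no 1x1x1 convolutions and no separate BN layers, and its
#' outputs agree with the training form (eval mode) to floating-point
#' accumulation error. Converting an already-deployed block is a no-op.
#'
#' @param block a `resrep_block`.
#' @return the deploy-form block.
#' @export
deploy_convert <- function(block) {
  if (isTRUE(block$deploy)) return(block)
  stem <- fold_bn(block$stem)
  structure(list(
    stem = list(kernel = stem$kernel, bias = stem$bias,
                stride = block$stem$stride, pad = block$stem$pad),
    stage_a = fuse_stage(block$stage_a),
    stage_b = fuse_stage(block$stage_b),
    in_ch = block$in_ch, out_ch = block$out_ch, deploy = TRUE
  ), class = "resrep_block")
}

#' @export
print.resrep_block <- function(x, ...) {
  cat(sprintf("<resrep_block> %d -> %d channels, %s form\n", x$in_ch, x$out_ch,
              if (isTRUE(x$deploy)) "deploy" else "train"))
  invisible(x)
}
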