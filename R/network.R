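# Whole-network assembly: five ResRep blocks, a four-block 3D residual stage,
# the NCSA block, global average pooling and a linear head, with deploy-time
# conversion and named feature taps.

#' Create a 3D basic residual block
#'
#' `relu(bn(conv3(relu(bn(conv3(x))))) + shortcut(x))` with a projection
#' shortcut (1x1x1 conv + BN) exactly when the block downsamples or changes
#' channels.
#'
#' @param in_ch,out_ch channel counts.
#' @param stride stride of the first convolution (and the projection).
#' @return object of class `resblock3d`.
#' @export
new_resblock3d <- function(in_ch, out_ch, stride = 1L) {
  needs_proj <- stride > 1L || in_ch != out_ch
  structure(list(
    conv1 = conv_bn(kaiming_kernel(3, in_ch, out_ch), stride = as.integer(stride)),
    conv2 = conv_bn(kaiming_kernel(3, out_ch, out_ch), stride = 1L),
    proj = if (needs_proj)
      conv_bn(kaiming_kernel(1, in_ch, out_ch), stride = as.integer(stride))
    else NULL,
    in_ch = in_ch, out_ch = out_ch, stride = as.integer(stride)
  ), class = "resblock3d")
}

#' 3D residual block forward pass
#'
#' @param x feature volume with `p$in_ch` channels.
#' @param p a [new_resblock3d()].
#' @param training use batch statistics in BN layers.
#' @param want_cache keep intermediates for backpropagation.
#' @return list with `y` (and `cache`, `params` when requested).
#' @export
resblock3d_forward <- function(x, p, training = FALSE, want_cache = FALSE) {
  if (fv_channels(x) != p$in_ch)
    stop(sprintf("resblock expects %d input channels, got %d", p$in_ch, fv_channels(x)),
         call. = FALSE)
  c1 <- conv_bn_forward(x, p$conv1, training, want_cache)
  r1 <- relu_forward(c1$y, want_cache)
  c2 <- conv_bn_forward(r1$y, p$conv2, training, want_cache)
  if (is.null(p$proj)) {
    sc <- x
    pc <- NULL
  } else {
    pj <- conv_bn_forward(x, p$proj, training, want_cache)
    sc <- pj$y
    pc <- pj$cache
    p$proj <- pj$params
  }
  pre <- c2$y + sc
  r2 <- relu_forward(pre, want_cache)
  p$conv1 <- c1$params
  p$conv2 <- c2$params
  cache <- if (want_cache)
    list(c1 = c1$cache, r1 = r1$cache, c2 = c2$cache, proj = pc, r2 = r2$cache)
  else NULL
  list(y = r2$y, cache = cache, params = p)
}

resblock3d_backward <- function(dy, p, cache) {
  dpre <- relu_backward(dy, cache$r2)
  g2 <- conv_bn_backward(dpre, p$conv2, cache$c2)
  dr1 <- relu_backward(g2$dx, cache$r1)
  g1 <- conv_bn_backward(dr1, p$conv1, cache$c1)
  grads <- list(conv1 = g1$grads, conv2 = g2$grads)
  if (is.null(p$proj)) {
    dx <- g1$dx + dpre
  } else {
    gp <- conv_bn_backward(dpre, p$proj, cache$proj)
    dx <- g1$dx + gp$dx
    grads$proj <- gp$grads
  }
  list(dx = dx, grads = grads)
}

#' Define the network architecture
#'
#' The canonical layout: four ResRep blocks (each halving the spatial
#' resolution with a stride-2 stem), a four-block 3D residual stage (first
#' block stride 2), a shape-preserving NCSA block, a fifth ResRep block,
#' global average pooling and a linear head with two outputs. `base_channels`
#' scales the whole channel progression `(1, 1, 2, 4, 8) * base_channels`.
#'
#' @param input_shape spatial input shape, default `c(121, 145, 121)`.
#' @param base_channels first-stage channel count (48 canonical, 6 reduced).
#' @param num_classes linear head width (2).
#' @param ncsa_mode,affinity_norm passed to [new_ncsa_params()].
#' @return object of class `architecture_spec` with a `stages` data.frame.
#' @export
architecture_spec <- function(input_shape = c(121, 145, 121), base_channels = 48,
                              num_classes = 2L, ncsa_mode = "key",
                              affinity_norm = "softmax") {
  ch <- base_channels * c(1, 1, 2, 4, 8)
  stages <- data.frame(
    name = c("rrb1", "rrb2", "rrb3", "rrb4", paste0("res", 1:4), "ncsa",
             "rrb5", "gap", "linear"),
    kind = c(rep("resrep", 4), rep("resblock3d", 4), "ncsa", "resrep", "gap", "linear"),
    in_ch = c(1, ch[1], ch[2], ch[3], rep(ch[4], 4), ch[4], ch[4], ch[5], ch[5]),
    out_ch = c(ch[1], ch[2], ch[3], ch[4], rep(ch[4], 4), ch[4], ch[5], ch[5], num_classes),
    stride = c(2, 2, 2, 2, 2, 1, 1, 1, 1, 2, 1, 1),
    stringsAsFactors = FALSE
  )
  spec <- structure(list(stages = stages, input_shape = input_shape,
                         num_classes = as.integer(num_classes),
                         base_channels = base_channels,
                         ncsa_mode = ncsa_mode, affinity_norm = affinity_norm),
                    class = "architecture_spec")
  validate_architecture_spec(spec)
  spec
}

#' Reduced desk-scale architecture preset
#'
#' Channels divided by 8 and a `(32, 40, 32)` input grid that keeps the
#' canonical aspect ratio; used for CPU training and tests.
#' @inheritParams architecture_spec
#' @export
reduced_architecture_spec <- function(input_shape = c(32, 40, 32),
                                      base_channels = 6,
                                      ncsa_mode = "key",
                                      affinity_norm = "softmax") {
  architecture_spec(input_shape = input_shape, base_channels = base_channels,
                    ncsa_mode = ncsa_mode, affinity_norm = affinity_norm)
}

validate_architecture_spec <- function(spec) {
  st <- spec$stages
  for (i in seq_len(nrow(st) - 1L)) {
    if (st$out_ch[i] != st$in_ch[i + 1L])
      stop(sprintf("incompatible stages: %s (out %d) -> %s (in %d)",
                   st$name[i], st$out_ch[i], st$name[i + 1L], st$in_ch[i + 1L]),
           call. = FALSE)
  }
  if (sum(st$kind == "ncsa") != 1L) stop("exactly one NCSA stage required", call. = FALSE)
  if (st$kind[nrow(st)] != "linear") stop("final stage must be linear", call. = FALSE)
  invisible(spec)
}

#' Predicted stage output shapes
#'
#' Applies the convolutional shape law
#' `floor((n + 2 pad - k)/stride) + 1` along the stage chain.
#'
#' @param spec an [architecture_spec()].
#' @return data.frame with stage name, output channels and output size.
#' @export
architecture_shapes <- function(spec) {
  st <- spec$stages
  sh <- spec$input_shape
  out <- vector("list", nrow(st))
  for (i in seq_len(nrow(st))) {
    kind <- st$kind[i]
    if (kind == "resrep" || kind == "resblock3d") {
      sh <- conv_out_dim(sh, 3, st$stride[i], 1)
    } else if (kind == "gap") sh <- c(1, 1, 1)
    out[[i]] <- list(name = st$name[i], out_ch = st$out_ch[i],
                     d1 = sh[1], d2 = sh[2], d3 = sh[3])
  }
  do.call(rbind, lapply(out, as.data.frame))
}

#' Build a network from an architecture spec
#'
#' Initializes all parameters (Kaiming-normal kernels, identity BN, zero NCSA
#' output projection) under an optional seed.
#'
#' @param spec an [architecture_spec()].
#' @param seed optional integer seed for the initialization.
#' @return object of class `resrepanet`.
#' @export
build_network <- function(spec = architecture_spec(), seed = NULL) {
  validate_architecture_spec(spec)
  mk <- function() {
    st <- spec$stages
    stages <- list()
    for (i in seq_len(nrow(st))) {
      nm <- st$name[i]
      stages[[nm]] <- switch(st$kind[i],
        resrep = new_resrep_block(st$in_ch[i], st$out_ch[i]),
        resblock3d = new_resblock3d(st$in_ch[i], st$out_ch[i], st$stride[i]),
        ncsa = new_ncsa_params(st$in_ch[i], spec$ncsa_mode, spec$affinity_norm),
        gap = list(),
        linear = list(W = matrix(stats::rnorm(st$in_ch[i] * st$out_ch[i],
                                              sd = sqrt(1 / st$in_ch[i])),
                                 st$in_ch[i], st$out_ch[i]),
                      b = rep(0, st$out_ch[i])))
    }
    stages
  }
  stages <- if (is.null(seed)) mk() else with_seed(seed, mk())
  structure(list(spec = spec, stages = stages, deploy = FALSE),
            class = "resrepanet")
}

#' @export
print.resrepanet <- function(x, ...) {
  sh <- architecture_shapes(x$spec)
  cat(sprintf("<resrepanet> base %d channels, input %s, %s form\n",
              x$spec$base_channels, paste(x$spec$input_shape, collapse = "x"),
              if (isTRUE(x$deploy)) "deploy" else "train"))
  print(sh, row.names = FALSE)
  invisible(x)
}

#' Network forward pass
#'
#' @param net a [build_network()] result (train or deploy form).
#' @param x feature volume `(d1, d2, d3, 1, batch)`.
#' @param training use batch statistics in BN layers.
#' @param want_cache keep intermediates for backpropagation.
#' @param want_taps also return per-stage activations.
#' @return list with `logits` (batch x 2), and `cache`, `net`, `taps` as
#'   requested.
#' @export
network_forward <- function(net, x, training = FALSE, want_cache = FALSE,
                            want_taps = FALSE) {
  check_feature_volume(x)
  st <- net$spec$stages
  caches <- list()
  taps <- list()
  h <- x
  feats <- NULL
  gap_spatial <- NULL
  for (i in seq_len(nrow(st))) {
    nm <- st$name[i]
    kind <- st$kind[i]
    if (kind == "resrep") {
      r <- resrep_block_forward(h, net$stages[[nm]], training, want_cache)
      h <- r$y
      net$stages[[nm]] <- r$params
      if (want_cache) caches[[nm]] <- r$cache
    } else if (kind == "resblock3d") {
      r <- resblock3d_forward(h, net$stages[[nm]], training, want_cache)
      h <- r$y
      net$stages[[nm]] <- r$params
      if (want_cache) caches[[nm]] <- r$cache
    } else if (kind == "ncsa") {
      r <- ncsa_forward(h, net$stages[[nm]], want_cache)
      if (want_cache) caches[[nm]] <- list(cache = r$cache, x_dim = dim(h))
      h <- r$y
    } else if (kind == "gap") {
      gap_spatial <- fv_spatial(h)
      feats <- gap_forward(h)$y
      h <- array(t(feats), c(1, 1, 1, ncol(feats), nrow(feats)))
    } else if (kind == "linear") {
      logits <- linear_forward(feats, net$stages[[nm]]$W, net$stages[[nm]]$b)$y
      if (want_cache) caches[[nm]] <- list(f = feats)
    }
    if (want_taps && kind != "linear") taps[[nm]] <- h
  }
  out <- list(logits = logits)
  if (want_cache) {
    caches$gap_spatial <- gap_spatial
    out$cache <- caches
    out$net <- net
  }
  if (want_taps) out$taps <- taps
  out
}

# Backward through the whole network. `tap_grad_stage` optionally records the
# gradient flowing into the named stage's *output* activation (Grad-CAM).
network_backward <- function(net, cache, dlogits, tap_grad_stage = NULL) {
  st <- net$spec$stages
  grads <- list()
  tap_grad <- NULL
  d <- NULL
  for (i in rev(seq_len(nrow(st)))) {
    nm <- st$name[i]
    kind <- st$kind[i]
    if (kind == "linear") {
      lb <- linear_backward(dlogits, cache[[nm]]$f, net$stages[[nm]]$W)
      grads[[nm]] <- list(W = lb$dW, b = lb$db)
      d <- lb$dx
    } else if (kind == "gap") {
      d <- gap_backward(d, cache$gap_spatial)
    } else if (kind == "ncsa") {
      r <- ncsa_backward(d, net$stages[[nm]], cache[[nm]]$cache, cache[[nm]]$x_dim)
      grads[[nm]] <- r$grads
      d <- r$dx
    } else if (kind == "resblock3d") {
      r <- resblock3d_backward(d, net$stages[[nm]], cache[[nm]])
      grads[[nm]] <- r$grads
      d <- r$dx
    } else if (kind == "resrep") {
      r <- resrep_block_backward(d, net$stages[[nm]], cache[[nm]])
      grads[[nm]] <- r$grads
      d <- r$dx
    }
    if (!is.null(tap_grad_stage) && i >= 2L && identical(tap_grad_stage, st$name[i - 1L]))
      tap_grad <- d
  }
  list(grads = grads, dx = d, tap_grad = tap_grad)
}

#' Convert a whole network to deploy form
#'
#' Every ResRep block is fused via [deploy_convert()]; residual blocks, NCSA,
#' pooling and the head are untouched. End-to-end outputs agree with the
#' training form (eval mode) to floating-point accumulation error.
#'
#' @param net a `resrepanet`.
#' @return the deploy-form network.
#' @export
deploy_network <- function(net) {
  st <- net$spec$stages
  for (i in which(st$kind == "resrep"))
    net$stages[[st$name[i]]] <- deploy_convert(net$stages[[st$name[i]]])
  net$deploy <- TRUE
  net
}

#' Per-stage feature taps
#'
#' Runs an eval-mode forward pass and returns copies of the named stage
#' outputs for visualization.
#'
#' @param net a `resrepanet`.
#' @param x input feature volume.
#' @param stages character vector of stage names (default: all except the
#'   head).
#' @return named list of feature volumes.
#' @export
feature_taps <- function(net, x, stages = NULL) {
  all_names <- setdiff(net$spec$stages$name, "linear")
  stages <- stages %||% all_names
  unknown <- setdiff(stages, all_names)
  if (length(unknown))
    stop(sprintf("unknown stage name(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  taps <- network_forward(net, x, training = FALSE, want_taps = TRUE)$taps
  taps[stages]
}

#' Count parameter values in a network or block
#'
#' @param x a network, block, or nested parameter list.
#' @return total number of numeric parameter values.
#' @export
count_parameters <- function(x) {
  if (inherits(x, "resrepanet")) x <- x$stages
  fl <- flatten_params(unclass(x))
  sum(vapply(fl, function(v) if (is.numeric(v)) length(v) else 0L, numeric(1)))
}

# number of parameter tensors (deploy-vs-train comparison)
count_tensors <- function(x) {
  if (inherits(x, "resrepanet")) x <- x$stages
  fl <- flatten_params(unclass(x))
  sum(vapply(fl, is.numeric, logical(1)))
}
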