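# Network assembly: residual blocks, the architecture shape chain, deploy
# equivalence, feature taps, determinism and end-to-end gradients.

test_that("resblock3d is the residual identity at zero weights and matches an
           unrolled reference", {
  set.seed(41)
  p <- new_resblock3d(3, 3, stride = 1L)
  # zero conv weights + identity shortcut: output is relu(x) = x for x >= 0
  p0 <- p
  p0$conv1$kernel[] <- 0
  p0$conv2$kernel[] <- 0
  x <- abs(rand_fv(4, 5, 4, 3, 2))
  expect_equal(resblock3d_forward(x, p0)$y, x)

  # random block equals the explicit two-conv + add computation
  rnd <- function(cb) {
    n <- dim(cb$kernel)[5]
    cb$bn_gamma <- runif(n, 0.5, 1.5); cb$bn_beta <- rnorm(n)
    cb$bn_mean <- rnorm(n); cb$bn_var <- runif(n, 0.2, 2)
    cb
  }
  p$conv1 <- rnd(p$conv1); p$conv2 <- rnd(p$conv2)
  xr <- rand_fv(4, 5, 4, 3, 2)
  h <- naive_bn_eval(conv3d(xr, p$conv1$kernel, NULL, 1, 1),
                     p$conv1$bn_gamma, p$conv1$bn_beta, p$conv1$bn_mean,
                     p$conv1$bn_var, p$conv1$bn_eps)
  h[h < 0] <- 0
  z <- naive_bn_eval(conv3d(h, p$conv2$kernel, NULL, 1, 1),
                     p$conv2$bn_gamma, p$conv2$bn_beta, p$conv2$bn_mean,
                     p$conv2$bn_var, p$conv2$bn_eps)
  want <- z + xr
  want[want < 0] <- 0
  expect_lt(max(abs(resblock3d_forward(xr, p)$y - want)), 1e-10)

  # projection shortcut appears exactly when needed
  expect_null(new_resblock3d(4, 4, 1L)$proj)
  expect_false(is.null(new_resblock3d(4, 4, 2L)$proj))
  expect_false(is.null(new_resblock3d(4, 8, 1L)$proj))
  expect_error(resblock3d_forward(rand_fv(4, 4, 4, 5), p), "channels")
})

test_that("the architecture spec validates stage compatibility", {
  spec <- architecture_spec()
  expect_silent(resrepanet:::validate_architecture_spec(spec))
  bad <- spec
  bad$stages$in_ch[3] <- 7
  expect_error(resrepanet:::validate_architecture_spec(bad), "incompatible stages")
})

test_that("the canonical shape chain follows the floor-division law", {
  sh <- architecture_shapes(architecture_spec())
  expect_equal(sh$d1, c(61, 31, 16, 8, 4, 4, 4, 4, 4, 2, 1, 1))
  expect_equal(sh$d2, c(73, 37, 19, 10, 5, 5, 5, 5, 5, 3, 1, 1))
  expect_equal(sh$out_ch[c(1, 4, 9, 10, 11, 12)], c(48, 192, 192, 384, 384, 2))
})

test_that("a reduced network runs forward with per-stage shapes and scaling law", {
  set.seed(42)
  spec <- reduced_architecture_spec()
  net <- build_network(spec, seed = 5)
  x <- rand_fv(32, 40, 32, 1, 2)
  t0 <- proc.time()
  out <- network_forward(net, x, want_taps = TRUE)
  expect_lt((proc.time() - t0)[3], 5)
  expect_equal(dim(out$logits), c(2, 2))
  sh <- architecture_shapes(spec)
  for (i in seq_len(nrow(sh) - 1)) {
    tp <- out$taps[[sh$name[i]]]
    expect_equal(dim(tp)[1:3], unlist(sh[i, c("d1", "d2", "d3")], use.names = FALSE))
    expect_equal(dim(tp)[4], sh$out_ch[i])
  }

  # halving the input shifts every stage by the same floor-division rule
  spec2 <- architecture_spec(input_shape = c(64, 80, 64), base_channels = 6)
  sh2 <- architecture_shapes(spec2)
  n <- c(64, 80, 64)
  for (i in 1:4) {
    n <- (n + 2 - 3) %/% 2 + 1
    expect_equal(unlist(sh2[i, c("d1", "d2", "d3")], use.names = FALSE), n)
  }
})

test_that("eval-mode forward is deterministic and taps are copies", {
  set.seed(43)
  net <- build_network(architecture_spec(input_shape = c(32, 40, 32),
                                         base_channels = 4), seed = 2)
  x <- rand_fv(32, 40, 32, 1, 1)
  t1 <- feature_taps(net, x, c("rrb1", "ncsa"))
  t2 <- feature_taps(net, x, c("rrb1", "ncsa"))
  expect_identical(t1, t2)
  expect_equal(length(t1), 2L)
  expect_equal(dim(t1$rrb1)[4], 4)
  t1$rrb1[] <- 99
  expect_false(identical(t1$rrb1, feature_taps(net, x, "rrb1")$rrb1))
  expect_error(feature_taps(net, x, "nope"), "unknown stage")
})

test_that("deploy_network matches the train form end to end", {
  set.seed(44)
  net <- build_network(architecture_spec(input_shape = c(32, 40, 32),
                                         base_channels = 4), seed = 3)
  # randomize running BN stats so folding is non-trivial
  fp <- resrepanet:::flatten_params(net$stages)
  for (nm in grep("bn_mean|\\.mean$", names(fp), value = TRUE))
    fp[[nm]] <- rnorm(length(fp[[nm]]), sd = 0.3)
  for (nm in grep("bn_var|\\.var$", names(fp), value = TRUE))
    fp[[nm]] <- runif(length(fp[[nm]]), 0.3, 1.5)
  net$stages <- resrepanet:::unflatten_params(fp, net$stages)
  dep <- deploy_network(net)
  worst <- 0
  decisions_equal <- TRUE
  for (r in 1:10) {
    x <- rand_fv(32, 40, 32, 1, 1)
    l1 <- network_forward(net, x)$logits
    l2 <- network_forward(dep, x)$logits
    worst <- max(worst, max(abs(l1 - l2)))
    decisions_equal <- decisions_equal && which.max(l1) == which.max(l2)
  }
  expect_lt(worst, 1e-8)
  expect_true(decisions_equal)
  expect_lt(resrepanet:::count_tensors(dep), resrepanet:::count_tensors(net))
})

test_that("network gradients agree with finite differences end to end", {
  set.seed(45)
  spec <- architecture_spec(input_shape = c(16, 32, 16), base_channels = 2)
  net <- build_network(spec, seed = 6)
  C <- net$spec$stages$in_ch[net$spec$stages$name == "ncsa"]
  net$stages$ncsa$out_proj$W <- matrix(rnorm(C * C, sd = 0.3), C, C)
  x <- rand_fv(16, 32, 16, 1, 2)
  y <- c(1, 0)
  lossfun <- function(nn) {
    fw <- network_forward(nn, x, training = TRUE, want_cache = TRUE)
    z <- fw$logits[, 2] - fw$logits[, 1]
    list(loss = -sum(y * plogis(z, log.p = TRUE) + (1 - y) * plogis(-z, log.p = TRUE)),
         fw = fw)
  }
  l0 <- lossfun(net)
  z <- l0$fw$logits[, 2] - l0$fw$logits[, 1]
  d <- plogis(z) - y
  bw <- resrepanet:::network_backward(net, l0$fw$cache, cbind(-d, d))
  fg <- resrepanet:::flatten_params(bw$grads)
  fp <- resrepanet:::flatten_params(net$stages)
  eps <- 1e-5
  sel <- c("rrb1.stem.kernel" = 14, "rrb2.stage_a.branch3.kernel" = 14,
           "rrb3.stage_b.branch_id.gamma" = 1, "res1.proj.kernel" = 1,
           "res2.conv2.kernel" = 14, "ncsa.theta.W" = 1,
           "ncsa.ctx_transform.ln_gamma" = 1, "ncsa.out_proj.W" = 2,
           "rrb5.stem.bn_beta" = 1, "linear.W" = 3)
  for (nm in names(sel)) {
    idx <- sel[[nm]]
    np <- fp; np[[nm]][idx] <- np[[nm]][idx] + eps
    n2 <- net; n2$stages <- resrepanet:::unflatten_params(np, n2$stages)
    lp <- lossfun(n2)$loss
    np[[nm]][idx] <- np[[nm]][idx] - 2 * eps
    n2$stages <- resrepanet:::unflatten_params(np, n2$stages)
    lm <- lossfun(n2)$loss
    num <- (lp - lm) / (2 * eps)
    expect_equal(fg[[nm]][idx], num, tolerance = 1e-3, label = nm)
  }
})

test_that("checkpoints round-trip through the flat named-array archive", {
  set.seed(46)
  net <- build_network(architecture_spec(input_shape = c(32, 40, 32),
                                         base_channels = 2), seed = 9)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(net, path)
  net2 <- load_checkpoint(path)
  x <- rand_fv(32, 40, 32, 1, 1)
  expect_equal(network_forward(net2, x)$logits, network_forward(net, x)$logits)
  # names follow the <stage>.<sub>.<branch>.<param> convention
  nm <- names(resrepanet:::flatten_params(net$stages))
  expect_true("rrb1.stage_a.branch3.kernel" %in% nm)
  expect_true("ncsa.ctx_transform.ln_gamma" %in% nm)
  unlink(path)
})
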