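# Structural re-parameterization: BN folding, kernel padding, identity
# kernels, stage fusion and block deploy conversion.

test_that("fold_bn reproduces hand-computed and two-step evaluations", {
  # scalar worked example: kernel 2, gamma 3, beta 1, mu 0.5, var 4, eps ~ 0
  # W' = 3/2 * 2 = 3; b' = beta - gamma * mu / sd = 1 - 3 * 0.5 / 2 = 0.25
  cb <- conv_bn(array(2, c(1, 1, 1, 1, 1)), bn_gamma = 3, bn_beta = 1,
                bn_mean = 0.5, bn_var = 4, bn_eps = 1e-12)
  f <- fold_bn(cb)
  expect_equal(as.numeric(f$kernel), 3, tolerance = 1e-9)
  expect_equal(f$bias, 0.25, tolerance = 1e-9)
  # cross-check the worked example against direct two-step evaluation
  x1 <- array(1.7, c(1, 1, 1, 1, 1))
  expect_equal(as.numeric(conv3d(x1, f$kernel, f$bias, 1, 0)),
               3 * (1.7 * 2 - 0.5) / 2 + 1, tolerance = 1e-9)

  # identity BN leaves the kernel untouched and the bias at zero
  set.seed(1)
  k <- resrepanet:::kaiming_kernel(3, 2, 3)
  cb2 <- conv_bn(k, bn_eps = 1e-12)
  f2 <- fold_bn(cb2)
  expect_equal(f2$kernel, k, tolerance = 1e-9)
  expect_equal(f2$bias, rep(0, 3), tolerance = 1e-9)

  # random ConvBN: folded conv == bn(conv(x)) via direct two-step evaluation
  cb3 <- random_conv_bn(3, 2, 4)
  x <- rand_fv(5, 6, 5, 2, 2)
  f3 <- fold_bn(cb3)
  two_step <- naive_bn_eval(conv3d(x, cb3$kernel, NULL, 1, 1),
                            cb3$bn_gamma, cb3$bn_beta, cb3$bn_mean,
                            cb3$bn_var, cb3$bn_eps)
  one_step <- conv3d(x, f3$kernel, f3$bias, 1, 1)
  expect_lt(max(abs(two_step - one_step)), 1e-10)

  # BN vector length mismatch is rejected
  expect_error(conv_bn(k, bn_gamma = rep(1, 2)), "output channel")
})

test_that("pad_1x1_to_3x3 preserves mass and the convolution result", {
  k1 <- array(5, c(1, 1, 1, 1, 1))
  k3 <- pad_1x1_to_3x3(k1)
  expect_equal(dim(k3), c(3, 3, 3, 1, 1))
  expect_equal(k3[2, 2, 2, 1, 1], 5)
  expect_equal(sum(k3), sum(k1))

  set.seed(2)
  kr <- array(rnorm(1 * 2 * 3), c(1, 1, 1, 2, 3))
  expect_equal(sum(pad_1x1_to_3x3(kr)), sum(kr))
  x <- rand_fv(4, 4, 4, 2)
  expect_lt(max(abs(conv3d(x, pad_1x1_to_3x3(kr), NULL, 1, 1) -
                    conv3d(x, kr, NULL, 1, 0))), 1e-12)

  expect_error(pad_1x1_to_3x3(array(1, c(3, 3, 3, 1, 1))), "spatial size")
})

test_that("identity_to_3x3 is the exact identity convolution", {
  K <- identity_to_3x3(2, 2)
  expect_equal(K[2, 2, 2, 1, 1], 1)
  expect_equal(K[2, 2, 2, 2, 2], 1)
  expect_equal(sum(K), 2)
  set.seed(3)
  x <- rand_fv(4, 5, 4, 2, 2)
  expect_equal(conv3d(x, K, NULL, 1, 1), x)
  expect_error(identity_to_3x3(2, 3), "in_ch == out_ch")

  # composed with fold_bn of an identity-BN branch it reproduces bn(x)
  bid <- list(gamma = runif(2, 0.5, 1.5), beta = rnorm(2), mean = rnorm(2),
              var = runif(2, 0.2, 2), eps = 1e-5)
  f <- fold_bn(resrepanet:::id_bn_as_conv_bn(bid, 2))
  got <- conv3d(x, f$kernel, f$bias, 1, 1)
  want <- naive_bn_eval(x, bid$gamma, bid$beta, bid$mean, bid$var, bid$eps)
  expect_lt(max(abs(got - want)), 1e-10)
})

test_that("fuse_stage exactly reproduces the multi-branch sum", {
  # identity BNs, no identity branch: fused kernel is K3 with the 1x1 weight
  # added at the center and zero bias
  set.seed(4)
  K3 <- resrepanet:::kaiming_kernel(3, 1, 1)
  w1 <- 0.7
  st0 <- rep_branch_params(conv_bn(K3, bn_var = rep(1, 1), bn_eps = 1e-12),
                           conv_bn(array(w1, c(1, 1, 1, 1, 1)), bn_eps = 1e-12))
  f0 <- fuse_stage(st0)
  want <- K3
  want[2, 2, 2, 1, 1] <- want[2, 2, 2, 1, 1] + w1
  expect_equal(f0$kernel, want, tolerance = 1e-9)
  expect_equal(f0$bias, 0, tolerance = 1e-9)

  # random two- and three-branch stages against the multi-branch forward
  for (with_id in c(FALSE, TRUE)) {
    st <- random_rep_stage(4, with_identity = with_id)
    x <- rand_fv(6, 7, 6, 4, 2)
    multi <- resrepanet:::rep_stage_forward(x, st)$y
    f <- fuse_stage(st)
    fused <- conv3d(x, f$kernel, f$bias, f$stride, f$pad)
    expect_lt(max(abs(multi - fused)), 1e-10)
  }
})

test_that("fusion exactness holds over many random stages and inputs", {
  set.seed(5)
  worst <- 0
  for (r in 1:25) {
    ch <- sample(2:6, 1)
    st <- random_rep_stage(ch, with_identity = r %% 2 == 0)
    x <- rand_fv(4, 5, 4, ch)
    multi <- resrepanet:::rep_stage_forward(x, st)$y
    f <- fuse_stage(st)
    fused <- conv3d(x, f$kernel, f$bias, 1, 1)
    worst <- max(worst, max(abs(multi - fused)))
  }
  expect_lt(worst, 1e-10)
})

test_that("resrep_block_forward matches the shape law and zero maps to zero", {
  set.seed(6)
  blk <- new_resrep_block(3, 5)
  x <- rand_fv(9, 11, 9, 3, 2)
  y <- resrep_block_forward(x, blk)$y
  expect_equal(dim(y), c(5, 6, 5, 5, 2))

  # all-zero input with zero shifts stays zero (beta = 0, mean = 0 defaults)
  x0 <- array(0, c(9, 11, 9, 3, 1))
  expect_equal(max(abs(resrep_block_forward(x0, blk)$y)), 0)

  expect_error(resrep_block_forward(rand_fv(9, 9, 9, 4), blk), "channels")
})

test_that("deploy_convert is exact, idempotent, and has the fused size", {
  set.seed(7)
  blk <- new_resrep_block(3, 4)
  # randomize BN statistics so folding is non-trivial
  rnd <- function(cb) {
    n <- dim(cb$kernel)[5]
    cb$bn_gamma <- runif(n, 0.5, 1.5); cb$bn_beta <- rnorm(n)
    cb$bn_mean <- rnorm(n); cb$bn_var <- runif(n, 0.2, 2)
    cb
  }
  blk$stem <- rnd(blk$stem)
  blk$stage_a$branch3 <- rnd(blk$stage_a$branch3)
  blk$stage_a$branch1 <- rnd(blk$stage_a$branch1)
  blk$stage_b$branch3 <- rnd(blk$stage_b$branch3)
  blk$stage_b$branch1 <- rnd(blk$stage_b$branch1)
  dep <- deploy_convert(blk)
  worst <- 0
  for (r in 1:10) {
    x <- rand_fv(8, 9, 8, 3)
    worst <- max(worst, max(abs(resrep_block_forward(x, blk)$y -
                                resrep_block_forward(x, dep)$y)))
  }
  expect_lt(worst, 1e-10)

  # deploy stage parameter count: out_ch * (in_ch * 27 + 1)
  expect_equal(length(dep$stage_a$kernel) + length(dep$stage_a$bias),
               4 * (4 * 27 + 1))
  # no 1x1x1 kernels or BN vectors remain
  expect_null(dep$stage_a$branch1)
  expect_null(dep$stem$bn_gamma)
  # idempotent
  expect_identical(deploy_convert(dep), dep)
})

test_that("identity branch construction is guarded", {
  expect_error(rep_branch_params(random_conv_bn(3, 2, 3),
                                 random_conv_bn(1, 2, 3),
                                 branch_id = resrepanet:::new_identity_bn(3)),
               "in_ch == out_ch")
})
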