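# Gradient density multi-weighting: norms, densities, harmonizing weights,
# maximum-entropy loss, partitions and baseline losses.

test_that("gradient_norm evaluates the sigmoid error", {
  expect_equal(gradient_norm(0, 1), 0.5)
  expect_lt(gradient_norm(20, 1), 1e-8)
  expect_equal(gradient_norm(c(0, 2.1972246), c(0, 1)), c(0.5, 0.1),
               tolerance = 1e-6)
  expect_error(gradient_norm(c(0, 1), c(0, 2)), "binary")
  expect_error(gradient_norm(c(Inf, 0), c(0, 1)), "finite")
})

test_that("gradient_density matches hand evaluation and the brute-force loop", {
  st <- new_gdmm_state(momentum = 0)
  norms <- c(0.05, 0.07, 0.12, 0.95)
  expect_equal(gradient_density(norms, st), c(20, 20, 10, 10))

  # all samples in one bin
  expect_equal(gradient_density(rep(0.33, 6), st), rep(6 / 0.1, 6))

  # vectorized result equals the literal double loop
  set.seed(31)
  for (r in 1:10) {
    nm <- runif(sample(2:40, 1))
    expect_equal(gradient_density(nm, new_gdmm_state(momentum = 0)),
                 brute_force_density(nm))
  }
  expect_error(gradient_density(numeric(0), st), "empty")
})

test_that("harmonizing weights follow W = N / GD and the occupancy identity", {
  st <- new_gdmm_state(momentum = 0)
  expect_equal(harmonizing_weights(rep(0.42, 5), st), rep(0.1, 5))
  norms <- c(0.05, 0.07, 0.12, 0.95)
  w <- harmonizing_weights(norms, st)
  expect_equal(w, c(0.2, 0.2, 0.4, 0.4))
  expect_equal(sum(w), 4 * 0.3)  # N x total occupied width

  # property: sum W = N x occupied width; all bins occupied implies sum = N
  set.seed(32)
  for (r in 1:10) {
    nm <- runif(30)
    st2 <- new_gdmm_state(momentum = 0)
    occupied <- length(unique(resrepanet:::bin_of(nm, 10))) * 0.1
    expect_equal(sum(harmonizing_weights(nm, st2)), 30 * occupied,
                 tolerance = 1e-10)
  }
  full <- (0:9 + 0.5) / 10
  expect_equal(sum(harmonizing_weights(full, st)), 10)
})

test_that("moving a sample into a denser bin strictly lowers its weight", {
  st <- new_gdmm_state(momentum = 0)
  norms <- c(0.05, 0.06, 0.07, 0.55, 0.95)   # bin 1 has 3 samples, bin 6 one
  w_sparse <- harmonizing_weights(norms, st)[4]
  norms2 <- norms; norms2[4] <- 0.04          # move sample 4 into crowded bin
  w_dense <- harmonizing_weights(norms2, st)[4]
  expect_lt(w_dense, w_sparse)
})

test_that("weights and loss are permutation equivariant", {
  set.seed(33)
  norms <- runif(20)
  logits <- rnorm(20)
  labels <- rbinom(20, 1, 0.5)
  perm <- sample(20)
  st <- new_gdmm_state(momentum = 0)
  expect_equal(harmonizing_weights(norms[perm], st),
               harmonizing_weights(norms, st)[perm])
  expect_equal(gdmm_loss(logits[perm], labels[perm], new_gdmm_state(momentum = 0)),
               gdmm_loss(logits, labels, new_gdmm_state(momentum = 0)))
})

test_that("max_entropy_loss evaluates stably and additively", {
  expect_equal(max_entropy_loss(20, 1), 0, tolerance = 1e-8)
  expect_equal(max_entropy_loss(0, 1), log(0.5))
  expect_equal(max_entropy_loss(0, 0), log(0.5))
  set.seed(34)
  z <- rnorm(12); y <- rbinom(12, 1, 0.5)
  expect_equal(max_entropy_loss(z, y),
               sum(vapply(seq_along(z), function(i) max_entropy_loss(z[i], y[i]),
                          numeric(1))))
  # extreme logits stay finite
  expect_true(is.finite(max_entropy_loss(c(-500, 500), c(0, 1))))
  # literal printed orientation is exposed for audit
  expect_equal(max_entropy_loss(0, 1, literal = TRUE),
               0.5 * plogis(1, log.p = TRUE) + 0.5 * plogis(-1, log.p = TRUE))
})

test_that("gdmm_loss reproduces the single-sample value and the CE reduction", {
  # one sample, logit 0, label 1: W = 0.1, term = -log 2
  st <- new_gdmm_state(momentum = 0)
  expect_equal(gdmm_loss(0, 1, st), 0.1 * log(2), tolerance = 1e-12)

  # saturated correct batch: near-zero loss
  st2 <- new_gdmm_state(momentum = 0)
  expect_lt(gdmm_loss(c(30, 30, -30), c(1, 1, 0), st2), 1e-6)

  # n_bins = 1 reduces to a constant rescaling of plain cross-entropy
  set.seed(35)
  for (r in 1:5) {
    z <- rnorm(16); y <- rbinom(16, 1, 0.3)
    st1 <- new_gdmm_state(n_bins = 1, momentum = 0)
    expect_equal(gdmm_loss(z, y, st1) / baseline_losses(z, y, "ce"), 1,
                 tolerance = 1e-10)
  }

  # loss is finite and non-negative for finite logits
  expect_gte(gdmm_loss(rnorm(8), rbinom(8, 1, 0.5), new_gdmm_state(momentum = 0)), 0)
})

test_that("EMA momentum carries bin counts across batches", {
  st <- new_gdmm_state(momentum = 0.75)
  gdmm_loss(rep(0, 4), rep(1, 4), st)  # all norms 0.5 -> bin 6
  expect_equal(st$ema_counts[6], 4)
  gdmm_loss(rep(0, 4), rep(0, 4), st)  # again bin 6 (norm 0.5)
  expect_equal(st$ema_counts[6], 4)    # same bin, EMA stationary
  gdmm_loss(c(20, 20, 20, 20), rep(1, 4), st)  # norms ~0 -> bin 1
  expect_equal(st$ema_counts[6], 0.75 * 4)
  expect_equal(st$ema_counts[1], 0.25 * 4)
})

test_that("difficulty_partition counts easy and hard regions", {
  expect_equal(unname(difficulty_partition(c(0.1, 0.4))), c(1, 1))
  expect_equal(unname(difficulty_partition(rep(0, 7))), c(7, 0))
  expect_equal(unname(difficulty_partition(c(0.05, 0.07, 0.12, 0.95))), c(3, 1))
})

test_that("baseline losses recover their limiting forms", {
  set.seed(36)
  z <- rnorm(10); y <- rbinom(10, 1, 0.5)
  expect_equal(baseline_losses(z, y, "focal", gamma = 0),
               baseline_losses(z, y, "ce"), tolerance = 1e-12)
  expect_equal(baseline_losses(z, y, "ce_label_smooth", alpha = 0),
               baseline_losses(z, y, "ce"), tolerance = 1e-12)
  expect_equal(baseline_losses(0, 1, "ce"), -log(0.5))
  expect_error(baseline_losses(z, y, "unknown"))
})

test_that("analytic loss gradients match finite differences for every kind", {
  set.seed(37)
  z <- rnorm(12); y <- rbinom(12, 1, 0.3)
  eps <- 1e-6
  for (kind in c("ce", "ce_label_smooth", "focal", "ghm", "gdmm")) {
    st <- new_gdmm_state(momentum = 0)
    lb <- resrepanet:::loss_forward_backward(z, y, kind, state = st, reduction = "sum")
    for (i in c(2, 7)) {
      f <- function(zz) {
        # weights are detached data: recompute them at the base point
        stx <- new_gdmm_state(momentum = 0)
        if (kind %in% c("gdmm", "ghm")) {
          w <- harmonizing_weights(abs(plogis(z) - y), stx)
          -sum(w * (y * plogis(zz, log.p = TRUE) + (1 - y) * plogis(-zz, log.p = TRUE)))
        } else if (kind == "ce") baseline_losses(zz, y, "ce")
        else if (kind == "ce_label_smooth") baseline_losses(zz, y, kind)
        else baseline_losses(zz, y, "focal")
      }
      zp <- z; zp[i] <- zp[i] + eps
      zm <- z; zm[i] <- zm[i] - eps
      expect_equal(lb$dlogits[i], (f(zp) - f(zm)) / (2 * eps), tolerance = 1e-4,
                   label = sprintf("d%s[%d]", kind, i))
    }
  }
})
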