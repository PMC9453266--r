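# Gradient Density Multi-weighting Mechanism (GDMM): per-sample gradient
# norms, histogram gradient density, inverse-density harmonizing weights, the
# maximum-entropy loss, and the baseline losses used for ablation (CE, CE with
# label smoothing, focal, gradient-harmonized CE).

#' Create a gradient-histogram state
#'
#' Holds the histogram configuration and, when `momentum > 0`, exponentially
#' smoothed bin counts carried across batches ("multi-batch weighting").
#' Implemented as an environment so the loss can update the EMA in place.
#'
#' @param n_bins number of equal-width bins spanning `[0, 1]` (default 10).
#' @param momentum EMA momentum in `[0, 1)`; 0 disables smoothing
#'   (default 0.75).
#' @param epsilon positive guard for the region width.
#' @param hard_bound easy/hard partition bound on the gradient norm
#'   (default 0.375).
#' @return environment of class `gdmm_state`.
#' @export
new_gdmm_state <- function(n_bins = 10L, momentum = 0.75, epsilon = 1e-6,
                           hard_bound = 0.375) {
  stopifnot(n_bins >= 1L, momentum >= 0, momentum < 1, epsilon > 0,
            hard_bound > 0, hard_bound < 1)
  e <- new.env(parent = emptyenv())
  e$n_bins <- as.integer(n_bins)
  e$bin_edges <- seq(0, 1, length.out = n_bins + 1L)
  e$momentum <- momentum
  e$epsilon <- epsilon
  e$hard_bound <- hard_bound
  e$ema_counts <- NULL
  e$counts <- rep(0L, n_bins)
  class(e) <- "gdmm_state"
  e
}

#' @export
print.gdmm_state <- function(x, ...) {
  cat(sprintf("<gdmm_state> %d bins on [0,1], momentum %.2f, hard bound %.3f\n",
              x$n_bins, x$momentum, x$hard_bound))
  invisible(x)
}

check_binary_labels <- function(labels) {
  if (!all(labels %in% c(0, 1)))
    stop("labels must be binary (0/1)", call. = FALSE)
}

#' Per-sample gradient norms
#'
#' The sample-difficulty proxy `|sigmoid(logit) - label|`, always in `[0, 1)`
#' for finite logits.
#'
#' @param logits real model scores (one logit per sample).
#' @param labels binary ground truth.
#' @return numeric vector of gradient norms.
#' @export
gradient_norm <- function(logits, labels) {
  if (!all(is.finite(logits))) stop("logits must be finite", call. = FALSE)
  check_binary_labels(labels)
  if (length(logits) != length(labels))
    stop("logits and labels must have equal length", call. = FALSE)
  abs(stats::plogis(logits) - labels)
}

bin_of <- function(norms, n_bins) pmin(floor(norms * n_bins) + 1L, n_bins)

#' Histogram gradient density
#'
#' Assigns the gradient norms to equal-width bins; a sample's density is the
#' (optionally EMA-smoothed) count of its bin divided by the bin's width
#' clipped to `[0, 1]`.
#'
#' @param norms gradient norms in `[0, 1]`.
#' @param state a [new_gdmm_state()].
#' @param update_state commit the EMA blend back into `state` (used by
#'   [gdmm_loss()]).
#' @return per-sample densities.
#' @export
gradient_density <- function(norms, state, update_state = FALSE) {
  if (length(norms) == 0L) stop("empty batch", call. = FALSE)
  if (any(norms < 0 | norms > 1)) stop("gradient norms must lie in [0, 1]", call. = FALSE)
  nb <- state$n_bins
  idx <- bin_of(norms, nb)
  counts <- tabulate(idx, nbins = nb)
  eff <- counts
  if (state$momentum > 0 && !is.null(state$ema_counts))
    eff <- state$momentum * state$ema_counts + (1 - state$momentum) * counts
  if (update_state) {
    state$counts <- counts
    if (state$momentum > 0)
      state$ema_counts <- if (is.null(state$ema_counts)) as.numeric(counts) else eff
  }
  width <- pmin(state$bin_edges[idx + 1L], 1) - pmax(state$bin_edges[idx], 0)
  width <- pmax(width, state$epsilon)
  eff[idx] / width
}

#' Harmonizing weights
#'
#' `W_n = N / GD(g_n)` with `N` the batch size: samples in crowded histogram
#' regions are down-weighted, samples in sparse regions up-weighted.
#'
#' @inheritParams gradient_density
#' @return per-sample positive weights.
#' @export
harmonizing_weights <- function(norms, state, update_state = FALSE) {
  gd <- gradient_density(norms, state, update_state = update_state)
  length(norms) / gd
}

max_entropy_terms <- function(logits, labels, literal = FALSE) {
  if (!all(is.finite(logits))) stop("logits must be finite", call. = FALSE)
  check_binary_labels(labels)
  if (literal) {
    p <- stats::plogis(logits)
    p * stats::plogis(labels, log.p = TRUE) +
      (1 - p) * stats::plogis(-labels, log.p = TRUE)
  } else {
    labels * stats::plogis(logits, log.p = TRUE) +
      (1 - labels) * stats::plogis(-logits, log.p = TRUE)
  }
}

#' Maximum-entropy (log-likelihood) loss
#'
#' Sum over samples of `y log(sigmoid(z)) + (1 - y) log(1 - sigmoid(z))`,
#' computed in numerically stable log-sigmoid form; always non-positive.
#' `literal = TRUE` evaluates the alternative printed orientation (label
#' inside the sigmoid-logs, prediction as multiplier) for audit.
#'
#' @inheritParams gradient_norm
#' @param literal audit variant flag.
#' @return scalar.
#' @export
max_entropy_loss <- function(logits, labels, literal = FALSE) {
  sum(max_entropy_terms(logits, labels, literal))
}

#' GDMM loss
#'
#' Negative harmonizing-weighted maximum-entropy sum:
#' `F_soft = -sum_n W_n [y_n log(sigmoid(z_n)) + (1-y_n) log(1-sigmoid(z_n))]`.
#' Weights are treated as data (detached); when `state$momentum > 0` the
#' state's EMA bin counts are updated in place as a side effect.
#'
#' @inheritParams gradient_norm
#' @param state a [new_gdmm_state()].
#' @param literal use the audit orientation of the maximum-entropy term.
#' @return scalar loss (non-negative in the default orientation).
#' @export
gdmm_loss <- function(logits, labels, state, literal = FALSE) {
  norms <- gradient_norm(logits, labels)
  w <- harmonizing_weights(norms, state, update_state = TRUE)
  -sum(w * max_entropy_terms(logits, labels, literal))
}

#' Easy/hard sample partition
#'
#' Counts of samples below/at-or-above the difficulty bound on the gradient
#' norm (diagnostic mirroring the gradient-norm histograms).
#'
#' @param norms gradient norms in `[0, 1]`.
#' @param hard_bound bound (default 0.375).
#' @return named integer vector `c(n_easy, n_hard)`.
#' @export
difficulty_partition <- function(norms, hard_bound = 0.375) {
  if (any(norms < 0 | norms > 1)) stop("gradient norms must lie in [0, 1]", call. = FALSE)
  c(n_easy = sum(norms < hard_bound), n_hard = sum(norms >= hard_bound))
}

#' Baseline classification losses
#'
#' Ablation comparators on a single sigmoid logit per sample (sum reduction):
#' `"ce"` plain cross-entropy; `"ce_label_smooth"` cross-entropy against
#' `y(1-alpha) + alpha/2`; `"focal"` cross-entropy scaled by `(1-p_t)^gamma`;
#' `"ghm"` gradient-harmonized cross-entropy using the same histogram
#' machinery as GDMM but without EMA smoothing.
#'
#' @inheritParams gradient_norm
#' @param kind one of `"ce"`, `"ce_label_smooth"`, `"focal"`, `"ghm"`.
#' @param alpha label-smoothing mass (default 0.1).
#' @param gamma focal exponent (default 2).
#' @param n_bins histogram bins for `"ghm"`.
#' @return scalar loss.
#' @export
baseline_losses <- function(logits, labels, kind = c("ce", "ce_label_smooth", "focal", "ghm"),
                            alpha = 0.1, gamma = 2, n_bins = 10L) {
  kind <- match.arg(kind)
  check_binary_labels(labels)
  lp <- stats::plogis(logits, log.p = TRUE)
  lq <- stats::plogis(-logits, log.p = TRUE)
  switch(kind,
    ce = -sum(labels * lp + (1 - labels) * lq),
    ce_label_smooth = {
      ys <- labels * (1 - alpha) + alpha / 2
      -sum(ys * lp + (1 - ys) * lq)
    },
    focal = {
      p <- stats::plogis(logits)
      pt <- labels * p + (1 - labels) * (1 - p)
      lpt <- labels * lp + (1 - labels) * lq
      -sum((1 - pt)^gamma * lpt)
    },
    ghm = {
      st <- new_gdmm_state(n_bins = n_bins, momentum = 0)
      w <- harmonizing_weights(gradient_norm(logits, labels), st)
      -sum(w * (labels * lp + (1 - labels) * lq))
    })
}

# loss value + d loss / d logits for the training loop; weights detached.
loss_forward_backward <- function(logits, labels, kind, state = NULL,
                                  alpha = 0.1, gamma = 2, reduction = "mean") {
  n <- length(logits)
  p <- stats::plogis(logits)
  if (kind == "gdmm") {
    norms <- abs(p - labels)
    w <- harmonizing_weights(norms, state, update_state = TRUE)
    loss <- -sum(w * max_entropy_terms(logits, labels))
    d <- w * (p - labels)
  } else if (kind == "ghm") {
    st <- new_gdmm_state(n_bins = if (is.null(state)) 10L else state$n_bins, momentum = 0)
    w <- harmonizing_weights(abs(p - labels), st)
    loss <- baseline_losses(logits, labels, "ghm", n_bins = st$n_bins)
    d <- w * (p - labels)
  } else if (kind == "ce") {
    loss <- baseline_losses(logits, labels, "ce")
    d <- p - labels
  } else if (kind == "ce_label_smooth") {
    ys <- labels * (1 - alpha) + alpha / 2
    loss <- baseline_losses(logits, labels, "ce_label_smooth", alpha = alpha)
    d <- p - ys
  } else if (kind == "focal") {
    pt <- labels * p + (1 - labels) * (1 - p)
    lpt <- labels * stats::plogis(logits, log.p = TRUE) +
      (1 - labels) * stats::plogis(-logits, log.p = TRUE)
    loss <- baseline_losses(logits, labels, "focal", gamma = gamma)
    # d/dpt of -(1-pt)^g log pt, then dpt/dz = (2y-1) p (1-p)
    dterm_dpt <- gamma * (1 - pt)^(gamma - 1) * lpt - (1 - pt)^gamma / pt
    d <- dterm_dpt * (2 * labels - 1) * p * (1 - p)
  } else stop(sprintf("unknown loss kind '%s'", kind), call. = FALSE)
  if (reduction == "mean") {
    loss <- loss / n
    d <- d / n
  }
  list(loss = loss, dlogits = d)
}
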