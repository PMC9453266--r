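# Training and evaluation pipeline: stratified splitting, SGD with momentum,
# weight decay and linear warmup, per-epoch metrics and gradient-histogram
# snapshots, checkpoint selection by validation AUC.

#' Training configuration
#'
#' Defaults are the full-scale training protocol: SGD with
#' momentum 0.9, weight decay 1e-8, initial learning rate 1e-4 with a linear
#' warmup, batch size 8, 300 epochs, 9:1 stratified train:validation split.
#' Desk-scale runs override `epochs`, `lr` and set `reduced = TRUE`.
#'
#' @param epochs training epochs (default 300).
#' @param batch_size minibatch size (default 8).
#' @param lr learning rate after warmup (default 1e-4).
#' @param warmup_epochs linear warmup length (default 5).
#' @param momentum SGD momentum (default 0.9).
#' @param weight_decay L2 penalty (default 1e-8).
#' @param loss one of `"gdmm"`, `"ce"`, `"ce_label_smooth"`, `"focal"`,
#'   `"ghm"`.
#' @param seed RNG seed for init, split and shuffling.
#' @param reduced use the reduced architecture preset.
#' @param split_ratio train fraction (default 0.9, i.e. 9:1).
#' @param threshold decision threshold on sigmoid scores.
#' @param gdmm_momentum EMA momentum of the GDMM histogram state.
#' @param n_bins GDMM histogram bins.
#' @param verbose print per-epoch progress.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 300L, batch_size = 8L, lr = 1e-4,
                         warmup_epochs = 5L, momentum = 0.9,
                         weight_decay = 1e-8, loss = "gdmm", seed = 1L,
                         reduced = FALSE, split_ratio = 0.9, threshold = 0.5,
                         gdmm_momentum = 0.75, n_bins = 10L, verbose = FALSE) {
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0, warmup_epochs >= 0,
            momentum >= 0, momentum < 1, weight_decay >= 0,
            split_ratio > 0, split_ratio < 1)
  loss <- match.arg(loss, c("gdmm", "ce", "ce_label_smooth", "focal", "ghm"))
  structure(as.list(environment()), class = "train_config")
}

# linear warmup to lr, then constant
lr_schedule <- function(epoch, cfg) {
  if (cfg$warmup_epochs > 0 && epoch <= cfg$warmup_epochs)
    cfg$lr * epoch / cfg$warmup_epochs
  else cfg$lr
}

# stratified train/validation split preserving the class ratio in both parts
stratified_split <- function(labels, train_frac, seed) {
  with_seed(seed, {
    idx1 <- which(labels == 1)
    idx0 <- which(labels == 0)
    n1 <- max(1L, round(length(idx1) * train_frac))
    n0 <- max(1L, round(length(idx0) * train_frac))
    tr <- c(sample(idx1, n1), sample(idx0, n0))
    list(train = sort(tr), val = sort(setdiff(seq_along(labels), tr)))
  })
}

# single logit from the 2-unit head: z = z_pos - z_neg (column 2 - column 1)
logits_to_z <- function(logits) logits[, 2] - logits[, 1]

sgd_update <- function(net, grads, vel, lr, momentum, weight_decay) {
  fg <- flatten_params(grads)
  fp <- flatten_params(net$stages)
  for (nm in names(fg)) {
    g <- fg[[nm]] + weight_decay * fp[[nm]]
    v <- if (is.null(vel[[nm]])) g * 0 else vel[[nm]]
    v <- momentum * v + g
    vel[[nm]] <- v
    fp[[nm]] <- fp[[nm]] - lr * v
  }
  net$stages <- unflatten_params(fp, net$stages)
  list(net = net, vel = vel)
}

#' Evaluate a network on a set of volumes
#'
#' @param net a `resrepanet`.
#' @param x feature volume batch `(d1,d2,d3,1,n)`.
#' @param labels binary labels.
#' @param threshold decision threshold.
#' @param batch_size forward batch size.
#' @return an `eval_report` with an additional `scores` field.
#' @export
evaluate_network <- function(net, x, labels, threshold = 0.5, batch_size = 8L) {
  n <- dim(x)[5]
  scores <- numeric(n)
  for (s in seq(1, n, by = batch_size)) {
    e <- min(n, s + batch_size - 1)
    xb <- x[, , , , s:e, drop = FALSE]
    z <- logits_to_z(network_forward(net, xb)$logits)
    scores[s:e] <- stats::plogis(z)
  }
  rep <- compute_metrics(scores, labels, threshold)
  rep$scores <- scores
  rep
}

#' Train a network on a phantom cohort
#'
#' SGD with momentum, weight decay and linear warmup on the configured loss;
#' the 2-unit head is mapped to a single sigmoid logit `z = z_AD - z_NC`.
#' Losses use mean reduction over the minibatch. Per-epoch training loss,
#' validation metrics and (for GDMM) gradient-histogram snapshots are logged;
#' the checkpoint with the best validation AUC is retained. Deterministic
#' given `config$seed` under single-threaded numerics.
#'
#' @param config a [train_config()].
#' @param cohort a [generate_cohort()] result (or a list with `x`
#'   `(d1,d2,d3,1,n)` and `labels`).
#' @param net optional pre-built network (default: built from the config).
#' @return list with `net` (final), `best_net`, `history` (per-epoch
#'   data.frame), `report` (validation report of the best net), `split`,
#'   `histograms`.
#' @export
train_network <- function(config, cohort, net = NULL) {
  data <- if (!is.null(cohort$volumes)) cohort_tensors(cohort) else cohort
  labels <- data$labels
  sp <- stratified_split(labels, config$split_ratio, derive_seed(config$seed, "split"))
  if (length(sp$train) == 0 || length(sp$val) == 0)
    stop("empty train or validation split", call. = FALSE)
  if (is.null(net)) {
    spec <- if (config$reduced) reduced_architecture_spec() else architecture_spec()
    net <- build_network(spec, seed = derive_seed(config$seed, "init"))
  }
  xtr <- data$x[, , , , sp$train, drop = FALSE]
  ytr <- labels[sp$train]
  xva <- data$x[, , , , sp$val, drop = FALSE]
  yva <- labels[sp$val]
  ntr <- length(ytr)
  state <- new_gdmm_state(n_bins = config$n_bins, momentum = config$gdmm_momentum)
  vel <- list()
  hist_rows <- list()
  histograms <- list()
  best <- list(auc = -Inf, net = net)
  for (epoch in seq_len(config$epochs)) {
    lr <- lr_schedule(epoch, config)
    ord <- with_seed(derive_seed(config$seed, paste0("epoch", epoch)), sample.int(ntr))
    ep_loss <- 0
    norms_epoch <- numeric(0)
    for (s in seq(1, ntr, by = config$batch_size)) {
      bi <- ord[s:min(ntr, s + config$batch_size - 1)]
      xb <- xtr[, , , , bi, drop = FALSE]
      yb <- ytr[bi]
      fw <- network_forward(net, xb, training = TRUE, want_cache = TRUE)
      net <- fw$net
      z <- logits_to_z(fw$logits)
      lb <- loss_forward_backward(z, yb, config$loss, state = state,
                                  reduction = "mean")
      if (!is.finite(lb$loss))
        stop(sprintf("non-finite loss at epoch %d (lr %.3g): aborting", epoch, lr),
             call. = FALSE)
      dlogits <- cbind(-lb$dlogits, lb$dlogits)
      bw <- network_backward(net, fw$cache, dlogits)
      up <- sgd_update(net, bw$grads, vel, lr, config$momentum, config$weight_decay)
      net <- up$net
      vel <- up$vel
      ep_loss <- ep_loss + lb$loss * length(bi)
      norms_epoch <- c(norms_epoch, abs(stats::plogis(z) - yb))
    }
    rep <- evaluate_network(net, xva, yva, config$threshold)
    hist_rows[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                     loss = ep_loss / ntr,
                                     val_acc = rep$acc, val_sen = rep$sen,
                                     val_spe = rep$spe, val_auc = rep$auc)
    histograms[[epoch]] <- gradient_histogram_snapshot(norms_epoch, state)
    if (!is.na(rep$auc) && rep$auc >= best$auc)  # ties: prefer the later, better-calibrated epoch
      best <- list(auc = rep$auc, net = net, report = rep, epoch = epoch)
    if (isTRUE(config$verbose))
      message(sprintf("epoch %3d lr %.2e loss %.4f val AUC %s",
                      epoch, lr, ep_loss / ntr, fmt_or_na(rep$auc)))
  }
  list(net = net, best_net = best$net, best_epoch = best$epoch,
       report = best$report, history = do.call(rbind, hist_rows),
       split = sp, histograms = histograms, gdmm_state = state)
}

#' Gradient-norm histogram snapshot
#'
#' Bin counts, densities and mean harmonizing weights of a set of gradient
#' norms (the per-epoch diagnostic mirrored by the loss-diagnostics export).
#'
#' @param norms gradient norms in `[0, 1]`.
#' @param state a [new_gdmm_state()] (its EMA is not modified).
#' @return data.frame with `bin_left`, `bin_right`, `count`, `density`,
#'   `mean_weight`, `region` (easy/hard).
#' @export
gradient_histogram_snapshot <- function(norms, state = new_gdmm_state(momentum = 0)) {
  nb <- state$n_bins
  edges <- state$bin_edges
  if (length(norms) == 0)
    return(data.frame(bin_left = edges[-(nb + 1)], bin_right = edges[-1],
                      count = 0L, density = 0, mean_weight = NA_real_,
                      region = ifelse(edges[-(nb + 1)] < state$hard_bound, "easy", "hard")))
  idx <- bin_of(norms, nb)
  counts <- tabulate(idx, nbins = nb)
  gd <- gradient_density(norms, state)
  w <- length(norms) / gd
  mw <- vapply(seq_len(nb), function(b) if (counts[b] > 0) mean(w[idx == b]) else NA_real_,
               numeric(1))
  data.frame(bin_left = edges[-(nb + 1)], bin_right = edges[-1],
             count = counts,
             density = counts / diff(edges),
             mean_weight = mw,
             region = ifelse(edges[-(nb + 1)] < state$hard_bound, "easy", "hard"))
}

# ---- checkpoints -----------------------------------------------------------

#' Save / load a network checkpoint
#'
#' The checkpoint is a flat named list of arrays
#' (`<stage>.<sub>.<branch>.<param>` naming) plus the architecture spec and a
#' `deploy` flag.
#'
#' @param net a `resrepanet`.
#' @param path file path (`.rds`).
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(list(params = flatten_params(net$stages),
               spec = net$spec, deploy = isTRUE(net$deploy)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path))
    stop(sprintf("checkpoint not found: %s", path), call. = FALSE)
  ck <- readRDS(path)
  net <- build_network(ck$spec)
  if (ck$deploy) net <- deploy_network(net)
  net$stages <- unflatten_params(ck$params, net$stages)
  net$deploy <- ck$deploy
  net
}
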