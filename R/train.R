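#' Training configuration for the enhanced model
#'
#' Defaults follow the published regime: batch size 128, weighted binary
#' cross-entropy, RAdam at learning rate 1e-3 with moment decay 0.9/0.999,
#' dynamic amplitude rescaling and Mixup augmentation, training stopped on
#' a training-loss plateau with the checkpoint taken at the highest
#' training AUC, and three-seed ensembling. No validation split is held
#' out — all data trains.
#'
#' @param batch_size examples per batch (>= 2, for Mixup pairing).
#' @param lr learning rate.
#' @param beta1,beta2 exponential decay rates of the first and second
#'   moment estimates.
#' @param optimizer `"radam"` or `"sgd_nesterov"`.
#' @param momentum Nesterov momentum (SGD only).
#' @param mixup_alpha Beta(alpha, alpha) Mixup parameter (0 disables).
#' @param rescale_range `(lo, hi)` amplitude factors for dynamic
#'   rescaling; `lo > 0`.
#' @param rescale_log draw the factor log-uniformly instead of uniformly.
#' @param class_weights `c(w_background, w_seizure)` or `NULL` to derive
#'   inverse class frequencies from the training set (renormalized so the
#'   mean example weight is 1).
#' @param n_seeds number of training seeds for the ensemble.
#' @param seeds explicit seed vector (overrides `n_seeds`).
#' @param plateau_patience epochs without sufficient loss decrease before
#'   stopping.
#' @param plateau_delta minimum loss decrease counting as progress.
#' @param max_epochs hard cap on epochs.
#' @param window_stride train on every `window_stride`-th window position
#'   (1 s-shifted windows overlap 15/16; a stride thins this redundancy).
#' @param channels_per_window randomly subsample this many channels per
#'   training window (`NULL` = all); a second thinning axis, since all
#'   channels of a window share one weak label.
#' @param auc_subsample number of training examples used for the per-epoch
#'   training-AUC checkpoint metric (`Inf` = all).
#' @return A validated `train_config` list.
#' @export
train_config <- function(batch_size = 128L, lr = 1e-3, beta1 = 0.9,
                         beta2 = 0.999, optimizer = "radam",
                         momentum = 0.9, mixup_alpha = 0.2,
                         rescale_range = c(0.5, 2), rescale_log = FALSE,
                         class_weights = NULL, n_seeds = 3L, seeds = NULL,
                         plateau_patience = 5L, plateau_delta = 1e-4,
                         max_epochs = 30L, window_stride = 1L,
                         channels_per_window = NULL,
                         auc_subsample = 4000L) {
  if (batch_size < 2L) stop("batch_size must be >= 2 for Mixup pairing")
  if (rescale_range[1L] <= 0 || rescale_range[1L] > rescale_range[2L])
    stop("rescale_range must satisfy 0 < lo <= hi")
  if (is.null(seeds)) seeds <- seq_len(n_seeds)
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 beta1 = beta1, beta2 = beta2, optimizer = optimizer,
                 momentum = momentum, mixup_alpha = mixup_alpha,
                 rescale_range = rescale_range, rescale_log = rescale_log,
                 class_weights = class_weights,
                 n_seeds = length(seeds), seeds = seeds,
                 plateau_patience = as.integer(plateau_patience),
                 plateau_delta = plateau_delta,
                 max_epochs = as.integer(max_epochs),
                 window_stride = as.integer(window_stride),
                 channels_per_window = channels_per_window,
                 auc_subsample = auc_subsample),
            class = "train_config")
}

#' Training configuration of the baseline model
#'
#' Batch size 300, plain stochastic gradient descent with learning rate
#' 0.001 and Nesterov momentum 0.9, Glorot uniform initialization.
#'
#' @param ... overrides passed to [train_config()].
#' @return A `train_config`.
#' @export
baseline_train_config <- function(...) {
  train_config(batch_size = 300L, lr = 0.001, optimizer = "sgd_nesterov",
               momentum = 0.9, mixup_alpha = 0, ...)
}

#' Mixup augmentation of a batch
#'
#' Draws one coefficient `lambda ~ Beta(alpha, alpha)` and a random pairing
#' permutation `pi`, then forms convex combinations
#' `x_i' = lambda x_i + (1-lambda) x_pi(i)` and likewise for the labels,
#' which thereby become soft. The batch label mass is conserved.
#'
#' @param x matrix `samples x batch`.
#' @param y numeric labels in `[0, 1]`, length `ncol(x)`.
#' @param alpha Beta parameter (> 0).
#' @param lambda optional fixed coefficient (bypasses the Beta draw).
#' @return List `(x, y, lambda)`.
#' @export
mixup_batch <- function(x, y, alpha = 0.2, lambda = NULL) {
  if (is.null(lambda)) {
    if (alpha <= 0) stop("alpha must be positive")
    lambda <- rbeta(1L, alpha, alpha)
  }
  perm <- sample.int(ncol(x))
  list(x = lambda * x + (1 - lambda) * x[, perm, drop = FALSE],
       y = lambda * y + (1 - lambda) * y[perm],
       lambda = lambda)
}

#' Dynamic amplitude rescaling
#'
#' Multiplies every example by its own random gain drawn from
#' `Uniform(lo, hi)` (or log-uniformly); labels are unchanged. Because the
#' networks take raw, un-normalized EEG, this is the mechanism that
#' exposes training to amplitude diversity.
#'
#' @param x matrix `samples x batch`.
#' @param range `(lo, hi)` with `lo > 0`.
#' @param log_uniform draw `g` log-uniformly.
#' @return Rescaled matrix.
#' @export
rescale_amplitude <- function(x, range = c(0.5, 2), log_uniform = FALSE) {
  if (range[1L] <= 0 || range[1L] > range[2L]) stop("invalid range")
  g <- if (log_uniform)
    exp(runif(ncol(x), log(range[1L]), log(range[2L])))
  else runif(ncol(x), range[1L], range[2L])
  x * rep(g, each = nrow(x))
}

#' Class-weighted binary cross-entropy
#'
#' Mean over the batch of `-(w1 y log p + w0 (1-y) log(1-p))`, with `p`
#' clipped away from 0 and 1. Soft (Mixup) targets are supported. With
#' inverse-frequency weights renormalized to mean example weight 1 this
#' counterbalances the seizure/background imbalance.
#'
#' @param y_true labels in `[0, 1]`.
#' @param p predicted probabilities.
#' @param w1,w0 seizure / background class weights.
#' @param eps clipping margin.
#' @return Scalar loss. `weighted_bce_grad()` returns dloss/dp (already
#'   divided by the batch size).
#' @export
weighted_bce <- function(y_true, p, w1 = 1, w0 = 1, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(w1 * y_true * log(p) + w0 * (1 - y_true) * log(1 - p))
}

#' @rdname weighted_bce
#' @export
weighted_bce_grad <- function(y_true, p, w1 = 1, w0 = 1, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  (-w1 * y_true / p + w0 * (1 - y_true) / (1 - p)) / length(p)
}

# inverse class frequencies, renormalized so mean example weight is 1
derive_class_weights <- function(y) {
  n <- length(y); n1 <- sum(y >= 0.5); n0 <- n - n1
  if (n1 == 0L || n0 == 0L)
    stop("training set must contain both classes")
  c(w0 = n / (2 * n0), w1 = n / (2 * n1))
}

# --- optimizers -----------------------------------------------------------

opt_step <- function(model, cfg, t) {
  if (cfg$optimizer == "radam") radam_step(model, cfg, t)
  else sgd_nesterov_step(model, cfg)
}

# Rectified Adam: warm-up heuristic controlling the variance of the
# adaptive learning rate; falls back to momentum SGD while the variance
# estimate is untrustworthy (rho_t <= 4).
radam_step <- function(model, cfg, t) {
  b1 <- cfg$beta1; b2 <- cfg$beta2
  rho_inf <- 2 / (1 - b2) - 1
  rho_t <- rho_inf - 2 * t * b2^t / (1 - b2^t)
  rect <- if (rho_t > 4)
    sqrt(((rho_t - 4) * (rho_t - 2) * rho_inf) /
         ((rho_inf - 4) * (rho_inf - 2) * rho_t))
  else NA_real_
  walk_layers(model$layers, function(l) {
    if (!length(l$params)) return()
    if (is.null(l$opt)) l$opt <- list()
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      st <- l$opt[[nm]]
      if (is.null(st)) st <- list(m = g * 0, v = g * 0)
      st$m <- b1 * st$m + (1 - b1) * g
      st$v <- b2 * st$v + (1 - b2) * g^2
      mhat <- st$m / (1 - b1^t)
      if (!is.na(rect)) {
        vhat <- sqrt(st$v / (1 - b2^t)) + 1e-8
        upd <- cfg$lr * rect * mhat / vhat
      } else {
        upd <- cfg$lr * mhat
      }
      l$params[[nm]] <- l$params[[nm]] - upd
      l$opt[[nm]] <- st
    }
  })
}

sgd_nesterov_step <- function(model, cfg) {
  mu <- cfg$momentum
  walk_layers(model$layers, function(l) {
    if (!length(l$params)) return()
    if (is.null(l$opt)) l$opt <- list()
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      v <- l$opt[[nm]]
      if (is.null(v)) v <- g * 0
      v <- mu * v - cfg$lr * g
      l$params[[nm]] <- l$params[[nm]] + mu * v - cfg$lr * g
      l$opt[[nm]] <- v
    }
  })
}

# --- training loop --------------------------------------------------------

#' Train a seizure-detection model
#'
#' Full-data training (no validation split): per batch, amplitude
#' rescaling then Mixup are applied on the fly, the class-weighted
#' cross-entropy is backpropagated and the optimizer steps. Training stops
#' once the epoch loss has failed to drop by `plateau_delta` for
#' `plateau_patience` consecutive epochs (or at `max_epochs`); the
#' returned weights are those of the epoch with the highest training AUC,
#' estimated on a fixed subsample of un-augmented training examples.
#'
#' @param arch `"enhanced"`, `"baseline"`, or a builder function.
#' @param ds a `windowed_dataset` containing both classes.
#' @param cfg a [train_config()].
#' @param seed integer seed fixing initialization, batch order and
#'   augmentation draws.
#' @param verbose print one line per epoch.
#' @return List with `model` (best-checkpoint weights restored), `history`
#'   (data.frame epoch/loss/auc), `checkpoint_epoch`, `class_weights`.
#' @export
train_model <- function(arch, ds, cfg = train_config(), seed = 1L,
                        verbose = FALSE) {
  ex <- if (inherits(ds, "windowed_dataset"))
    with_seed(seed, flatten_examples(ds, cfg$window_stride,
                                     cfg$channels_per_window))
  else ds
  train_examples(arch, ex$x, ex$y, cfg, seed, verbose)
}

# x: samples x n_examples, y: 0/1 labels
train_examples <- function(arch, x, y, cfg, seed, verbose = FALSE) {
  with_seed(seed, {
    builder <- if (is.function(arch)) arch
    else switch(arch, enhanced = build_enhanced,
                baseline = build_baseline, stop("unknown arch ", arch))
    model <- builder()
    cw <- if (is.null(cfg$class_weights)) derive_class_weights(y)
    else c(w0 = cfg$class_weights[1L], w1 = cfg$class_weights[2L])
    n <- length(y)
    n_auc <- min(n, cfg$auc_subsample)
    auc_idx <- sort(sample.int(n, n_auc))
    if (length(unique(y[auc_idx])) < 2L) auc_idx <- seq_len(n)

    history <- data.frame(epoch = integer(), loss = numeric(),
                          auc = numeric())
    best_auc <- -Inf; best_w <- NULL; best_epoch <- 0L
    best_loss <- Inf; stale <- 0L; t_step <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      losses <- numeric()
      for (i0 in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[i0:min(n, i0 + cfg$batch_size - 1L)]
        if (length(idx) < 2L) next
        xb <- x[, idx, drop = FALSE]
        yb <- y[idx]
        xb <- rescale_amplitude(xb, cfg$rescale_range, cfg$rescale_log)
        if (cfg$mixup_alpha > 0) {
          mb <- mixup_batch(xb, yb, cfg$mixup_alpha)
          xb <- mb$x; yb <- mb$y
        }
        xb <- array(xb, dim = c(nrow(xb), 1L, length(idx)))
        p <- as.numeric(nn_forward(model$layers, xb, training = TRUE))
        losses <- c(losses, weighted_bce(yb, p, cw["w1"], cw["w0"]))
        dp <- weighted_bce_grad(yb, p, cw["w1"], cw["w0"])
        nn_backward(model$layers, matrix(dp, nrow = 1L))
        t_step <- t_step + 1L
        opt_step(model, cfg, t_step)
      }
      epoch_loss <- mean(losses)
      auc <- roc_auc(y[auc_idx],
                     predict_examples(model, x[, auc_idx, drop = FALSE]))
      history <- rbind(history,
                       data.frame(epoch = epoch, loss = epoch_loss,
                                  auc = auc))
      if (verbose)
        message(sprintf("epoch %d  loss %.4f  auc %.4f", epoch,
                        epoch_loss, auc))
      if (auc > best_auc) {
        best_auc <- auc; best_w <- get_weights(model); best_epoch <- epoch
      }
      if (epoch_loss < best_loss - cfg$plateau_delta) {
        best_loss <- epoch_loss; stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= cfg$plateau_patience) break
      }
    }
    set_weights(model, best_w)
    clear_caches(model)
    list(model = model, history = history, checkpoint_epoch = best_epoch,
         class_weights = cw)
  })
}

#' Train a multi-seed ensemble
#'
#' Trains one model per seed in `cfg$seeds`; at inference the member
#' probabilities are averaged, damping the sensitivity of results to
#' weight initialization and data order.
#'
#' @inheritParams train_model
#' @return List of `train_model()` results, class `seizure_ensemble`.
#' @export
train_ensemble <- function(arch, ds, cfg = train_config(),
                           verbose = FALSE) {
  fits <- lapply(cfg$seeds, function(s)
    train_model(arch, ds, cfg, seed = s, verbose = verbose))
  structure(fits, class = "seizure_ensemble")
}

#' Averaged per-window probabilities of an ensemble
#'
#' Arithmetic mean of the member models' per-(window, channel)
#' probabilities, computed before channel fusion and before any
#' postprocessing.
#'
#' @param models a `seizure_ensemble`, or list of models / of
#'   `train_model()` results.
#' @param ds a `windowed_dataset`.
#' @return Matrix `n_windows x n_channels`.
#' @export
ensemble_predict <- function(models, ds) {
  models <- as_model_list(models)
  if (!length(models)) stop("empty model list")
  ps <- lapply(models, predict_windows, ds = ds)
  Reduce(`+`, ps) / length(ps)
}

as_model_list <- function(models) {
  if (inherits(models, "seizure_model")) return(list(models))
  lapply(models, function(m)
    if (inherits(m, "seizure_model")) m else m$model)
}
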