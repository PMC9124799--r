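#' Training configuration
#'
#' Bundles the loss configurations and optimization constants of the
#' training loop. Defaults follow the reference hyperparameter set:
#' Adam on the network weights with learning rate `lr_w = 1.915e-3`,
#' plain gradient descent on the ensemble weights with
#' `lr_lam = 2e-3`, firing-rate target 20 Hz with scale 1.0, voltage
#' regularization 1e-2.
#'
#' @param ensemble An [ensemble_loss_config()].
#' @param correntropy A [correntropy_config()].
#' @param regularizer A [regularizer_config()].
#' @param batch_size Trials per iteration.
#' @param lr_w Adam learning rate for the weights.
#' @param lr_lam Gradient-descent rate for the ensemble weights.
#' @param grad_clip Global-norm clip for weight gradients.
#' @param lam_grad_clip Per-coordinate clip for the ensemble-weight
#'   gradient (the rate regularizer can be orders of magnitude larger than
#'   the other base losses early in training).
#' @param decision_window Fraction of the trial over which the readout is
#'   averaged for the classification decision.
#' @return An object of class `train_config`.
#' @export
train_config <- function(ensemble = ensemble_loss_config(),
                         correntropy = correntropy_config(),
                         regularizer = regularizer_config(),
                         batch_size = 16, lr_w = 1.915e-3, lr_lam = 2e-4,
                         grad_clip = 100, lam_grad_clip = 10,
                         decision_window = 0.5) {
  structure(list(ensemble = ensemble, correntropy = correntropy,
                 regularizer = regularizer, batch_size = batch_size,
                 lr_w = lr_w, lr_lam = lr_lam, grad_clip = grad_clip,
                 lam_grad_clip = lam_grad_clip,
                 decision_window = decision_window),
            class = "train_config")
}

# Assemble a batch input array and one-hot labels from a pattern dataset.
.sample_pattern_batch <- function(dataset, batch_size) {
  cls <- sample.int(dataset$n_classes, batch_size, replace = TRUE)
  ids <- sample.int(dataset$n_per_class, batch_size, replace = TRUE)
  Tn <- as.integer(round(dataset$duration_ms / dataset$dt))
  x <- array(0, c(batch_size, dataset$n_neurons, Tn))
  for (b in seq_len(batch_size)) {
    r <- as_spike_raster(dataset$instances[[cls[b]]][[ids[b]]])
    x[b, , ] <- matrix(r, dim(r)[2], dim(r)[3])
  }
  onehot <- matrix(0, batch_size, dataset$n_classes)
  onehot[cbind(seq_len(batch_size), cls)] <- 1
  list(x = x, classes = cls, onehot = onehot)
}

# Readout decision: softmax over the readout averaged across the final
# decision window. Returns probabilities and the gradient spreading map.
.decision_probs <- function(rollout, window) {
  Tn <- rollout$T
  t0 <- max(1L, Tn - as.integer(round(window * Tn)) + 1L)
  steps <- t0:Tn
  ybar <- apply(rollout$y[, , steps, drop = FALSE], c(1, 2), mean)
  list(probs = softmax(ybar), steps = steps, ybar = ybar)
}

# Gradient of (lam1^2 * MMCC + lam2^2 * CE) with respect to the readout
# trace, through the softmax and the decision-window average.
.classification_g_y <- function(rollout, dec, onehot, lam, cfg) {
  B <- nrow(dec$probs); K <- ncol(dec$probs)
  p <- dec$probs
  g_p <- matrix(0, B, K)
  if (lam[1] != 0) {
    l1 <- mmcc_loss(onehot, p, cfg$correntropy, gradient = TRUE)
    g_p <- g_p + lam[1]^2 * attr(l1, "gradient")
  }
  # mean cross-entropy with softmax upstream collapses to (p - y)/B
  g_s_ce <- if (lam[2] != 0) lam[2]^2 * (p - onehot) / B else 0
  # push the MMCC part through the softmax Jacobian
  g_s <- p * (g_p - rowSums(g_p * p)) + g_s_ce
  g_y <- array(0, c(B, K, rollout$T))
  per_step <- g_s / length(dec$steps)
  for (t in dec$steps) g_y[, , t] <- per_step
  g_y
}

# Direct gradients of the two regularizers with respect to spikes (rate)
# and membrane potential / threshold (voltage), already weighted by lam^2.
# Like the voltage penalty, the trained rate loss is normalized by
# batch x time so its gradient scale is commensurate with the task losses.
.regularizer_grads <- function(rollout, reg, lam, dt) {
  d <- dim(rollout$z)
  B <- d[1]; N <- d[2]; Tn <- d[3]
  out <- list(g_z = NULL, g_v = NULL, g_A = NULL,
              rate_loss = 0, volt_loss = 0, rates = NULL)
  rl <- rate_regularizer(rollout$z, reg, dt = dt)
  out$rate_loss <- as.numeric(rl) / (B * Tn)
  out$rates <- attr(rl, "rates")
  if (lam[3] != 0) {
    gf <- lam[3]^2 * reg$lam_f * 2 * (out$rates - reg$f_target) /
      (B * Tn * dt / 1000) / (B * Tn)
    out$g_z <- array(rep(gf, each = B), c(B, N, Tn))
  }
  out$volt_loss <- voltage_regularizer(rollout$v, rollout$A, reg)
  if (lam[4] != 0) {
    nt <- B * Tn
    over <- pmax(rollout$v - rollout$A, 0)
    under <- pmax(-rollout$v - reg$v_th, 0)
    out$g_v <- lam[4]^2 * reg$lam_v / nt * (2 * over - 2 * under)
    out$g_A <- lam[4]^2 * reg$lam_v / nt * (-2 * over)
  }
  out
}

#' Train a recurrent spiking network on spike-pattern classification
#'
#' The joint training loop: per iteration a mini-batch of noisy pattern
#' instances is drawn, the network is rolled out, the four base losses
#' (mixture-correntropy and cross-entropy on the softmax of the
#' time-averaged readout, firing-rate and voltage regularizers on the
#' hidden dynamics) are combined by the ensemble objective, gradients flow
#' back through surrogate-gradient BPTT, the weights are updated by Adam
#' and the ensemble weights by plain gradient descent. Deterministic given
#' the seed.
#'
#' @param network An [snn_network()] whose input size matches the dataset's
#'   neurons and output size the number of classes.
#' @param dataset A `spike_pattern_dataset` with instances.
#' @param cfg A [train_config()].
#' @param n_iters Number of outer iterations (0 returns the initialization).
#' @param seed Integer seed for batch sampling and the ensemble-weight
#'   initialization.
#' @param log_every Record a log row every this many iterations.
#' @param init Optional `snn_training` object from a previous call:
#'   training resumes bit-exactly (weights, ensemble weights, optimizer
#'   moments and random-number state are restored, and iteration
#'   numbering continues).
#' @return An object of class `snn_training`: the trained `network`,
#'   final ensemble weights `lam`, and `log`, a data frame with columns
#'   `iteration`, `L1..L4`, `lam1..lam4`, `penalty`, `total`, `accuracy`,
#'   `mean_rate_hz`.
#' @export
train_network <- function(network, dataset, cfg = train_config(),
                          n_iters = 100, seed = 1L, log_every = 1L,
                          init = NULL) {
  if (!is.null(init)) network <- init$network
  stopifnot(network$n_in == dataset$n_neurons)
  iter0 <- 0L
  if (is.null(init)) {
    set.seed(as.integer(seed))
    lam <- cfg$ensemble$lam
    pars <- network$weights[c("W_in", "W_rec", "W_out", "b_out")]
    opt <- adam_init(pars)
  } else {
    assign(".Random.seed", init$rng, envir = globalenv())
    lam <- init$lam
    pars <- network$weights[c("W_in", "W_rec", "W_out", "b_out")]
    opt <- init$opt
    iter0 <- init$iter_end
  }
  log <- vector("list", n_iters)
  for (it in seq_len(n_iters)) {
    batch <- .sample_pattern_batch(dataset, cfg$batch_size)
    ro <- simulate_network(network, batch$x)
    dec <- .decision_probs(ro, cfg$decision_window)
    L1 <- as.numeric(mmcc_loss(batch$onehot, dec$probs, cfg$correntropy))
    L2 <- cross_entropy(batch$onehot, dec$probs)
    rg <- .regularizer_grads(ro, cfg$regularizer, lam, dt = network$params$dt)
    base <- c(L1, L2, rg$rate_loss, rg$volt_loss)
    ecfg <- cfg$ensemble; ecfg$lam <- lam
    bd <- ensemble_objective(base, ecfg)
    if (!is.finite(bd$total))
      stop(sprintf("training diverged (non-finite total loss) at iteration %d", it))
    g_y <- .classification_g_y(ro, dec, batch$onehot, lam, cfg)
    bp <- surrogate_bptt(ro, network, g_y = g_y, g_z = rg$g_z,
                         g_v = rg$g_v, g_A = rg$g_A)
    grads <- clip_gradients(bp$grads[names(pars)], cfg$grad_clip)
    upd <- adam_step(opt, pars, grads, cfg$lr_w)
    pars <- upd$params; opt <- upd$opt
    network$weights[names(pars)] <- pars
    diag(network$weights$W_rec) <- 0
    if (cfg$ensemble$trainable) {
      lam <- update_ensemble_weights(lam, base, ecfg$eta1, ecfg$eta2,
                                     cfg$lr_lam, clip = cfg$lam_grad_clip)
    }
    if (it %% log_every == 0 || it == n_iters) {
      acc <- mean(max.col(dec$probs, ties.method = "first") == batch$classes)
      log[[it]] <- data.frame(iteration = iter0 + it, L1 = base[1], L2 = base[2],
                              L3 = base[3], L4 = base[4],
                              lam1 = lam[1], lam2 = lam[2], lam3 = lam[3],
                              lam4 = lam[4], penalty = bd$penalty,
                              total = bd$total, accuracy = acc,
                              mean_rate_hz = mean(rg$rates))
    }
  }
  structure(list(network = network, lam = lam,
                 log = do.call(rbind, log[!vapply(log, is.null, logical(1))]),
                 cfg = cfg, seed = as.integer(seed), opt = opt,
                 rng = get(".Random.seed", envir = globalenv()),
                 iter_end = iter0 + n_iters),
            class = "snn_training")
}

#' @export
print.snn_training <- function(x, ...) {
  n <- nrow(x$log)
  cat(sprintf("snn_training: %d logged iterations; final total loss %.4g, accuracy %.3f, mean rate %.1f Hz\n",
              n, x$log$total[n], x$log$accuracy[n], x$log$mean_rate_hz[n]))
  invisible(x)
}

#' Evaluate a trained classifier on freshly sampled pattern instances
#'
#' @param network A trained [snn_network()].
#' @param dataset A `spike_pattern_dataset`.
#' @param n_trials Number of held-out trials to draw.
#' @param cfg A [train_config()] (for the decision window).
#' @param seed Integer seed.
#' @return List with `accuracy`, `mean_rate_hz` and the per-neuron `rates`
#'   over the evaluation batch.
#' @export
evaluate_classifier <- function(network, dataset, n_trials = 32,
                                cfg = train_config(), seed = 1L) {
  set.seed(as.integer(seed))
  batch <- .sample_pattern_batch(dataset, n_trials)
  ro <- simulate_network(network, batch$x)
  dec <- .decision_probs(ro, cfg$decision_window)
  rates <- firing_rates(ro, dt = network$params$dt)
  list(accuracy = mean(max.col(dec$probs, ties.method = "first") == batch$classes),
       mean_rate_hz = mean(rates), rates = rates)
}
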