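#' Learner/teacher network pair for learning-to-learn
#'
#' Constructs the two coupled recurrent spiking networks of the
#' learning-to-learn architecture: the learner (HSNN, a mix of
#' two-compartment and plain LIF neurons) which produces the task output,
#' and the teacher (PSNN, LIF) which observes the learner's spikes plus
#' task/label channels during the first phase of an episode and emits one
#' low-pass-filtered learning signal per learner neuron through its
#' readout. Learning signals flow from teacher to learner only, and only
#' in phase 1. A fraction `q_ada` of the neurons in each pool carries an
#' adaptive threshold (assigned at random, seeded).
#'
#' @param n_input Number of learner input channels (task channels + phase
#'   bit for matching episodes; clock channels for motor episodes).
#' @param n_out Learner readout size (1 for matching, 2 for motor
#'   commands).
#' @param n_extra_psnn Number of teacher-only channels appended after the
#'   learner-spike channels (phase bit + label channel for matching;
#'   trial bit + 2 target-coordinate channels for motor).
#' @param n_tlif,n_lif Learner pool sizes (two-compartment / plain).
#' @param n_psnn Teacher size.
#' @param q_ada Fraction of adaptive-threshold neurons in each pool.
#' @param params A `neuron_params` (shared by both networks except that
#'   the teacher readout time constant is the learning-signal constant
#'   `tau_ls`).
#' @param dparams A `dendrite_params` for the two-compartment pool.
#' @param tau_ls Learning-signal filter time constant (ms).
#' @param task `"matching"` or `"motor"`.
#' @param gain Weight-initialization gain (see [network_weights()]).
#' @param seed Integer seed for initialization.
#' @return An object of class `meta_networks` with elements `hsnn`,
#'   `psnn` (both [snn_network()]) and bookkeeping fields.
#' @export
meta_networks <- function(n_input, n_out = 1, n_extra_psnn = 2,
                          n_tlif = 180, n_lif = 260, n_psnn = 239,
                          q_ada = 0.405, params = neuron_params(),
                          dparams = dendrite_params(), tau_ls = 10,
                          task = c("matching", "motor"),
                          gain = 1, seed = 1L) {
  task <- match.arg(task)
  set.seed(as.integer(seed))
  n_h <- n_tlif + n_lif
  kind <- rep(c("tlif", "lif"), c(n_tlif, n_lif))
  ada_h <- rep(FALSE, n_h)
  if (n_tlif > 0)
    ada_h[sample.int(n_tlif, round(q_ada * n_tlif))] <- TRUE
  if (n_lif > 0)
    ada_h[n_tlif + sample.int(n_lif, round(q_ada * n_lif))] <- TRUE
  ada_p <- rep(FALSE, n_psnn)
  ada_p[sample.int(n_psnn, round(q_ada * n_psnn))] <- TRUE
  w_h <- network_weights(n_input, n_h, n_out,
                         seed = sample.int(2^30, 1), gain = gain)
  psnn_params <- params
  psnn_params$tau_out <- tau_ls
  psnn_params$nu <- exp(-params$dt / tau_ls)
  w_p <- network_weights(n_h + n_extra_psnn, n_psnn, n_h,
                         seed = sample.int(2^30, 1), gain = gain)
  structure(list(
    hsnn = snn_network(w_h, params, dparams, kind = kind, adaptive = ada_h),
    psnn = snn_network(w_p, psnn_params, kind = "lif", adaptive = ada_p),
    n_input = n_input, n_out = n_out, n_extra_psnn = n_extra_psnn,
    task = task, tau_ls = tau_ls, seed = as.integer(seed)
  ), class = "meta_networks")
}

#' @export
print.meta_networks <- function(x, ...) {
  cat(sprintf("meta_networks (%s task): learner %d neurons (%d tlif + %d lif), teacher %d neurons\n",
              x$task, x$hsnn$n_rec, sum(x$hsnn$kind == "tlif"),
              sum(x$hsnn$kind == "lif"), x$psnn$n_rec))
  invisible(x)
}

#' Meta-learning configuration
#'
#' @param eta_inner Inner-loop rate scaling the learning-signal x
#'   eligibility weight change applied at the phase boundary. Its absolute
#'   scale is not critical: the outer loop can rescale the teacher's
#'   readout weights.
#' @param lr_w Adam learning rate for all outer-loop weights.
#' @param lr_lam Gradient-descent rate for the ensemble weights.
#' @param ensemble,correntropy,regularizer,regularizer_psnn Loss
#'   configurations (the teacher has its own target rate).
#' @param grad_clip,lam_grad_clip Gradient clips (see [train_config()]).
#' @return An object of class `meta_config`.
#' @export
meta_config <- function(eta_inner = 1e-2, lr_w = 2e-3, lr_lam = 2e-4,
                        ensemble = ensemble_loss_config(),
                        correntropy = correntropy_config(),
                        regularizer = regularizer_config(),
                        regularizer_psnn = regularizer_config(f_target = 20),
                        grad_clip = 100, lam_grad_clip = 10) {
  structure(list(eta_inner = eta_inner, lr_w = lr_w, lr_lam = lr_lam,
                 ensemble = ensemble, correntropy = correntropy,
                 regularizer = regularizer,
                 regularizer_psnn = regularizer_psnn,
                 grad_clip = grad_clip, lam_grad_clip = lam_grad_clip),
            class = "meta_config")
}

# ---- episode batch assembly -------------------------------------------------

# Stack matching episodes into batched input arrays.
.matching_batch <- function(nets, episodes) {
  B <- length(episodes)
  ep1 <- episodes[[1]]
  T1 <- ep1$t_phase1
  T2 <- ep1$n_way * ep1$t_item
  n_in <- nrow(ep1$input)
  stopifnot(n_in == nets$n_input)
  X1 <- array(0, c(B, n_in, T1))
  X2 <- array(0, c(B, n_in, T2))
  labels <- matrix(0, B, ep1$n_way)
  for (b in seq_len(B)) {
    ep <- episodes[[b]]
    X1[b, , ] <- ep$input[, seq_len(T1)]
    X2[b, , ] <- ep$input[, T1 + seq_len(T2)]
    labels[b, ] <- ep$labels
  }
  # teacher extras: phase bit (0) and a label channel marking the support;
  # when the teacher's input block is sized n_input + 2 it additionally
  # receives the raw episode channels
  n_extra <- nets$n_extra_psnn
  Xp_extra <- array(0, c(B, n_extra, T1))
  Xp_extra[, n_extra, ] <- 1
  if (n_extra == n_in + 2) {
    Xp_extra[, seq_len(n_in), ] <- X1
  } else if (n_extra != 2) {
    stop("teacher extra channels must be 2 or n_input + 2 for matching")
  }
  sample_steps <- ep1$t_item * seq_len(ep1$n_way) # relative to phase-2 start
  list(B = B, T1 = T1, T2 = T2, X1 = X1, X2 = X2, Xp_extra = Xp_extra,
       labels = labels, sample_steps = sample_steps,
       match = vapply(episodes, `[[`, integer(1), "match"))
}

# Stack motor tasks: same clock input in both trials; teacher sees the
# target trajectory during the training trial.
.motor_batch <- function(nets, tasks) {
  B <- length(tasks)
  tk1 <- tasks[[1]]
  Tn <- ncol(tk1$clock_input)
  n_in <- nrow(tk1$clock_input)
  stopifnot(n_in == nets$n_input)
  X <- array(0, c(B, n_in, Tn))
  Xp_extra <- array(0, c(B, 3, Tn))
  omega <- array(0, c(B, 2, Tn))
  for (b in seq_len(B)) {
    tk <- tasks[[b]]
    X[b, , ] <- tk$clock_input
    # target coordinates as injected currents, amplified so the analog
    # drive is commensurate with the spiking background the teacher sees
    Xp_extra[b, 2, ] <- 5 * tk$target_trajectory[, 1]
    Xp_extra[b, 3, ] <- 5 * tk$target_trajectory[, 2]
    omega[b, , ] <- t(tk$target_velocities)
  }
  list(B = B, T1 = Tn, T2 = Tn, X1 = X, X2 = X, Xp_extra = Xp_extra,
       omega = omega, tasks = tasks)
}

# ---- inner eligibility ------------------------------------------------------

# Presynaptic traces for the inner eligibility: the alpha-filtered input
# trace (input synapses carry no delay) and the alpha-filtered learner
# spikes lagged by the transmission delay, stacked as a B x P x T1 array
# (p runs over input channels then learner neurons).
.inner_pre_traces <- function(params, X1, z_h) {
  p <- params; d <- p$d
  B <- dim(X1)[1]; T1 <- dim(X1)[3]
  n_in <- dim(X1)[2]; N <- dim(z_h)[2]
  ZL <- array(0, c(B, n_in + N, T1))
  zb_in <- matrix(0, B, n_in)
  zb_rec <- matrix(0, B, N)
  hist <- vector("list", T1)
  for (t in seq_len(T1)) {
    zb_in <- p$alpha * zb_in + matrix(X1[, , t], B)
    zb_rec <- p$alpha * zb_rec + matrix(z_h[, , t], B)
    hist[[t]] <- zb_rec
    ZL[, seq_len(n_in), t] <- zb_in
    if (t > d) ZL[, n_in + seq_len(N), t] <- hist[[t - d]]
  }
  ZL
}

# Inner-eligibility scan over phase 1. The synapse eligibility is
# e_jp(t) = psi_j(t) * (pre_p(t) - beta_j * eps_a_jp(t)), with eps_a the
# adaptation component advanced as
# eps_a(t) = (rho - beta psi(t-1)) eps_a(t-1) + psi(t-1) pre(t-1).
# Two modes share the scan:
#  * LS given  -> returns M[b, j, p] = sum_t LS_j(t) e_jp(t)  (forward);
#  * dM given  -> returns dLS[b, j, t] = sum_p dM[b, j, p] e_jp(t)
#                 (backward, eligibility treated as constant).
# The non-adaptive part collapses to one matrix product per episode; only
# the adaptive rows carry the eps_a recursion.
.inner_eligibility_scan <- function(params, beta_j, psi, X1, z_h,
                                    LS = NULL, dM = NULL) {
  p <- params
  B <- dim(X1)[1]; T1 <- dim(X1)[3]
  n_in <- dim(X1)[2]; N <- dim(z_h)[2]
  P <- n_in + N
  ZL <- .inner_pre_traces(p, X1, z_h)
  mode_M <- !is.null(LS)
  ada <- which(beta_j != 0)
  N_a <- length(ada)
  if (mode_M) {
    LSpsi <- LS * psi
    M <- array(0, c(B, N, P))
    for (b in seq_len(B))
      M[b, , ] <- tcrossprod(matrix(LSpsi[b, , ], N, T1),
                             matrix(ZL[b, , ], P, T1))
  } else {
    dLS <- array(0, c(B, N, T1))
    for (b in seq_len(B))
      dLS[b, , ] <- matrix(dM[b, , ], N, P) %*% matrix(ZL[b, , ], P, T1)
    dLS <- dLS * psi
  }
  if (N_a > 0 && T1 > 1) {
    idxB <- rep(seq_len(B), times = N_a)
    beta_a <- rep(beta_j[ada], each = B)
    E <- matrix(0, B * N_a, P)
    if (mode_M) {
      Macc <- matrix(0, B * N_a, P)
    } else {
      dM_E <- matrix(dM[, ada, ], B * N_a, P)
      corr <- matrix(0, B * N_a, T1)
    }
    for (t in 2:T1) {
      psi_prev <- c(psi[, ada, t - 1])
      E <- E * (p$rho - beta_a * psi_prev) +
        psi_prev * matrix(ZL[, , t - 1], B)[idxB, , drop = FALSE]
      if (mode_M) {
        wgt <- c(LS[, ada, t]) * c(psi[, ada, t]) * beta_a
        Macc <- Macc + wgt * E
      } else {
        corr[, t] <- rowSums(dM_E * E)
      }
    }
    if (mode_M) {
      M[, ada, ] <- M[, ada, , drop = FALSE] - array(Macc, c(B, N_a, P))
    } else {
      sub <- array(corr, c(B, N_a, T1)) * psi[, ada, , drop = FALSE] *
        rep(beta_j[ada], each = B)
      dLS[, ada, ] <- dLS[, ada, , drop = FALSE] - sub
    }
  }
  if (mode_M) M else dLS
}

# ---- forward ----------------------------------------------------------------

#' Run the two-phase inner trial of the learning-to-learn architecture
#'
#' Phase 1 (training trial): the learner is driven by the episode input
#' while the teacher observes the learner's spikes plus the task/label
#' channels and emits per-learner-neuron learning signals through its
#' low-pass readout. At the phase boundary the learner's input and
#' recurrent weights receive a three-factor update, `delta W_ji =
#' -eta_inner * sum_t LS_j(t) e_ji(t)`, the product of each synapse's
#' eligibility trace with its postsynaptic learning signal. Phase 2 (test
#' trial): the learner runs with the updated weights and no learning
#' signals; its readout is the episode output.
#'
#' @param nets A [meta_networks()].
#' @param episodes For the matching task a list of [build_episode()]
#'   objects; for the motor task a list of [generate_motor_task()] objects.
#' @param cfg A [meta_config()].
#' @param inner_update Apply the phase-boundary weight update (set `FALSE`
#'   to measure the learner's pre-update behavior).
#' @return A list with phase-1/2 rollouts for both networks, the learning
#'   signals `LS` (`batch x learner-neurons x T1`, identically zero in
#'   phase 2 by construction), per-episode weight updates `dW`, phase-2
#'   readout `y2` and, per task, decision scores or motor trajectories.
#' @export
run_inner_trial <- function(nets, episodes, cfg = meta_config(),
                            inner_update = TRUE) {
  if (inherits(episodes, c("fewshot_episode", "arm_task")))
    episodes <- list(episodes)
  batch <- if (nets$task == "matching") .matching_batch(nets, episodes)
           else .motor_batch(nets, episodes)
  .meta_forward(nets, batch, cfg, inner_update = inner_update)
}

.meta_forward <- function(nets, batch, cfg, inner_update = TRUE) {
  hs <- nets$hsnn; ps <- nets$psnn
  B <- batch$B; T1 <- batch$T1; T2 <- batch$T2
  N <- hs$n_rec
  carry <- nets$task == "matching"

  ro_h1 <- simulate_network(hs, batch$X1)
  # teacher input: learner spikes delayed one step, then extras
  Xp <- array(0, c(B, N + nets$n_extra_psnn, T1))
  if (T1 > 1) Xp[, seq_len(N), 2:T1] <- ro_h1$z[, , 1:(T1 - 1)]
  Xp[, N + seq_len(nets$n_extra_psnn), ] <- batch$Xp_extra
  ro_p <- simulate_network(ps, Xp)
  LS <- ro_p$y # batch x N x T1, already low-pass filtered (tau_ls readout)

  dW <- vector("list", B)
  if (inner_update && cfg$eta_inner != 0) {
    M <- .inner_eligibility_scan(hs$params, hs$beta, ro_h1$psi,
                                 batch$X1, ro_h1$z, LS = LS)
    for (b in seq_len(B)) {
      dWb <- -cfg$eta_inner * t(matrix(M[b, , ], N)) # P x N
      dW[[b]] <- list(W_in = dWb[seq_len(nets$n_input), , drop = FALSE],
                      W_rec = dWb[nets$n_input + seq_len(N), , drop = FALSE])
      diag(dW[[b]]$W_rec) <- 0
    }
  } else {
    zero <- list(W_in = matrix(0, nets$n_input, N), W_rec = matrix(0, N, N))
    for (b in seq_len(B)) dW[[b]] <- zero
  }

  # phase 2: batched rollout with per-episode weight deltas
  d <- hs$params$d
  if (carry) {
    z_pre <- array(0, c(B, N, d))
    for (k in seq_len(d)) z_pre[, , k] <- ro_h1$z[, , T1 - k + 1]
    ro2 <- .phase2_forward(hs, batch$X2, dW, state0 = ro_h1$state,
                           y0 = matrix(ro_h1$y[, , T1], B, nets$n_out),
                           z_pre = z_pre, filt0 = ro_h1$filt_state)
  } else {
    ro2 <- .phase2_forward(hs, batch$X2, dW)
  }
  y2 <- ro2$y
  z2 <- ro2$z
  out <- list(batch = batch, ro_h1 = ro_h1, ro_p = ro_p, LS = LS,
              LS_phase2 = array(0, c(B, N, T2)), dW = dW,
              ro_h2 = ro2, y2 = y2, z2 = z2, carry = carry)
  if (nets$task == "matching") {
    scores <- matrix(0, B, length(batch$sample_steps))
    for (n in seq_along(batch$sample_steps))
      scores[, n] <- stats::plogis(y2[, 1, batch$sample_steps[n]])
    out$scores <- scores
    out$decision <- max.col(scores, ties.method = "first")
  } else {
    out$trajectories <- lapply(seq_len(B), function(b)
      integrate_motor_commands(batch$tasks[[b]]$initial_angles,
                               t(matrix(y2[b, , ], nets$n_out)),
                               batch$tasks[[b]]$link_lengths,
                               dt = hs$params$dt)$trajectory)
  }
  out
}

# Batched phase-2 rollout: all episodes advance together; the per-episode
# inner updates enter as low-rank drive corrections (input-weight deltas
# are precomputed per episode, recurrent deltas applied per step).
.phase2_forward <- function(network, X2, dW, state0 = NULL, y0 = NULL,
                            z_pre = NULL, filt0 = NULL) {
  p <- network$params
  w <- network$weights
  B <- dim(X2)[1]; Tn <- dim(X2)[3]
  N <- network$n_rec; K <- network$n_out
  d <- p$d
  any_filt <- any(network$filtered_input)
  x_filt <- NULL; filt_state <- NULL
  if (any_filt) {
    fs <- .filter_with_state(X2, network$dparams, dt = p$dt, state = filt0)
    x_filt <- fs$out; filt_state <- fs$state
  }
  fmask_col <- network$filtered_input
  # per-episode input-delta drive over all steps
  DIN <- array(0, c(B, N, Tn))
  for (b in seq_len(B)) {
    din <- t(matrix(X2[b, , ], dim(X2)[2], Tn)) %*% dW[[b]]$W_in # T x N
    if (any_filt) {
      dinf <- t(matrix(x_filt[b, , ], dim(X2)[2], Tn)) %*% dW[[b]]$W_in
      din[, fmask_col] <- dinf[, fmask_col]
    }
    DIN[b, , ] <- t(din)
  }
  st <- if (is.null(state0)) neuron_state(B, N, p$v_th) else state0
  y <- if (is.null(y0)) matrix(w$b_out, B, K, byrow = TRUE) else y0
  Dm <- matrix(network$decay, B, N, byrow = TRUE)
  Gi <- matrix(network$in_gain, B, N, byrow = TRUE)
  Gr <- matrix(network$rec_gain, B, N, byrow = TRUE)
  Bm <- matrix(network$beta, B, N, byrow = TRUE)
  b_in <- matrix(w$b_in, B, N, byrow = TRUE)
  fmask <- matrix(fmask_col, B, N, byrow = TRUE)
  Z <- V <- A <- PSI <- array(0, c(B, N, Tn))
  Y <- array(0, c(B, K, Tn))
  for (t in seq_len(Tn)) {
    xt <- matrix(X2[, , t], B)
    drive <- xt %*% w$W_in
    if (any_filt) {
      drive_f <- matrix(x_filt[, , t], B) %*% w$W_in
      drive[fmask] <- drive_f[fmask]
    }
    drive <- drive + matrix(DIN[, , t], B)
    zd <- if (t > d) {
      matrix(Z[, , t - d], B)
    } else if (!is.null(z_pre)) {
      matrix(z_pre[, , d - t + 1], B)
    } else {
      matrix(0, B, N)
    }
    rec <- zd %*% w$W_rec
    for (b in seq_len(B)) rec[b, ] <- rec[b, ] + zd[b, ] %*% dW[[b]]$W_rec
    st$a <- p$mu * st$a + st$z
    st$A <- Bm * st$a + p$v_th
    st$v <- Dm * (st$v - p$v_th * st$z) + Gi * (drive + b_in) + rec * Gr
    st <- .emit_spikes(st, p)
    y <- readout_update(y, st$z, w, p)
    if (anyNA(st$v)) stop(sprintf("numerical failure at phase-2 step %d", t))
    Z[, , t] <- st$z; V[, , t] <- st$v; A[, , t] <- st$A
    PSI[, , t] <- 0.3 * pmax(1 - abs(st$A - st$v) / p$v_th, 0) * st$can_spike
    Y[, , t] <- y
  }
  structure(list(z = Z, v = V, A = A, psi = PSI, y = Y, x = X2,
                 x_filt = x_filt, state = st, n_batch = B, T = Tn,
                 z_pre = z_pre, filt_state = filt_state,
                 y_continued = !is.null(y0)),
            class = "snn_rollout")
}

# Batched phase-2 backward mirroring surrogate_bptt, with the per-episode
# recurrent-delta term in the spike credit and per-episode weight-delta
# gradients extracted from stacked time courses. Base-weight gradients
# equal the per-episode sums (W2_b = W + dW_b).
.phase2_backward <- function(rollout, network, dW, g_y = NULL, g_z = NULL,
                             g_v = NULL, g_A = NULL,
                             return_boundary = FALSE) {
  p <- network$params
  w <- network$weights
  B <- rollout$n_batch; Tn <- rollout$T
  N <- network$n_rec; K <- network$n_out
  n_in <- dim(rollout$x)[2]
  d <- p$d
  Dm <- matrix(network$decay, B, N, byrow = TRUE)
  Gi <- matrix(network$in_gain, B, N, byrow = TRUE)
  Gr <- matrix(network$rec_gain, B, N, byrow = TRUE)
  Bm <- matrix(network$beta, B, N, byrow = TRUE)
  raw_mask_col <- !network$filtered_input
  any_filt <- any(network$filtered_input)
  tWrec <- t(w$W_rec)
  tWout <- t(w$W_out)
  tdWrec <- lapply(dW, function(dw) t(dw$W_rec))
  zero_N <- matrix(0, B, N)
  gW_out <- matrix(0, N, K)
  gb_out <- numeric(K)
  dv_buf <- vector("list", Tn + d)
  da_buf <- vector("list", Tn + 1)
  for (i in seq_along(dv_buf)) dv_buf[[i]] <- zero_N
  for (i in seq_along(da_buf)) da_buf[[i]] <- zero_N
  gacc_y <- matrix(0, B, K)
  DvGr <- array(0, c(B, N, Tn)) # dv * rec_gain stack for weight grads
  DvGi <- array(0, c(B, N, Tn))
  slice <- function(arr, t, nc) if (is.null(arr)) NULL else matrix(arr[, , t], B, nc)
  for (t in Tn:1) {
    gy_t <- slice(g_y, t, K)
    gacc_y <- p$nu * gacc_y
    if (!is.null(gy_t)) gacc_y <- gacc_y + gy_t
    gb_out <- gb_out + (1 - p$nu) * colSums(gacc_y)
    psi_t <- matrix(rollout$psi[, , t], B, N)
    dz <- (1 - p$nu) * (gacc_y %*% tWout) + da_buf[[t + 1]]
    if (t + d <= Tn) {
      dvn <- dv_buf[[t + d]] * Gr
      dz <- dz + dvn %*% tWrec
      for (b in seq_len(B)) dz[b, ] <- dz[b, ] + dvn[b, ] %*% tdWrec[[b]]
    }
    gz_t <- slice(g_z, t, N)
    if (!is.null(gz_t)) dz <- dz + gz_t
    dA <- -psi_t * dz
    gA_t <- slice(g_A, t, N)
    if (!is.null(gA_t)) dA <- dA + gA_t
    dv <- psi_t * dz
    gv_t <- slice(g_v, t, N)
    if (!is.null(gv_t)) dv <- dv + gv_t
    if (t + 1 <= Tn) dv <- dv + Dm * dv_buf[[t + 1]]
    da <- Bm * dA + p$mu * da_buf[[t + 1]]
    dv_buf[[t]] <- dv
    da_buf[[t]] <- da
    gW_out <- gW_out + (1 - p$nu) * crossprod(matrix(rollout$z[, , t], B, N),
                                              gacc_y)
    DvGr[, , t] <- dv * Gr
    DvGi[, , t] <- dv * Gi
  }
  gy0 <- p$nu * gacc_y
  if (!isTRUE(rollout$y_continued)) gb_out <- gb_out + colSums(gy0)
  # per-episode weight-delta gradients from stacked time courses
  ddW <- vector("list", B)
  gW_in <- matrix(0, n_in, N)
  gW_rec <- matrix(0, N, N)
  for (b in seq_len(B)) {
    Zd <- matrix(0, Tn, N) # z(t - d) rows
    if (Tn > d) Zd[(d + 1):Tn, ] <- t(matrix(rollout$z[b, , seq_len(Tn - d)], N))
    if (!is.null(rollout$z_pre)) {
      for (k in seq_len(min(d, Tn)))
        Zd[k, ] <- rollout$z_pre[b, , d - k + 1]
    }
    DvGr_b <- t(matrix(DvGr[b, , ], N, Tn))
    g_rec_b <- crossprod(Zd, DvGr_b)
    diag(g_rec_b) <- 0
    DvGi_b <- t(matrix(DvGi[b, , ], N, Tn)) # T x N
    Xb <- t(matrix(rollout$x[b, , ], n_in, Tn)) # T x n_in
    if (any_filt) {
      Mraw <- matrix(raw_mask_col, Tn, N, byrow = TRUE)
      Xfb <- t(matrix(rollout$x_filt[b, , ], n_in, Tn))
      g_in_b <- crossprod(Xb, DvGi_b * Mraw) + crossprod(Xfb, DvGi_b * !Mraw)
    } else {
      g_in_b <- crossprod(Xb, DvGi_b)
    }
    ddW[[b]] <- list(W_in = g_in_b, W_rec = g_rec_b)
    gW_in <- gW_in + g_in_b
    gW_rec <- gW_rec + g_rec_b
  }
  out <- list(grads = list(W_in = gW_in, W_rec = gW_rec, W_out = gW_out,
                           b_out = gb_out),
              ddW = ddW)
  if (return_boundary) {
    dz_pre <- array(0, c(B, N, d))
    for (k in seq_len(d)) {
      tt <- 1 - k + d
      acc <- if (tt >= 1 && tt <= Tn) {
        dvn <- dv_buf[[tt]] * Gr
        a2 <- dvn %*% tWrec
        for (b in seq_len(B)) a2[b, ] <- a2[b, ] + dvn[b, ] %*% tdWrec[[b]]
        a2
      } else {
        zero_N
      }
      if (k == 1) acc <- acc + da_buf[[1]]
      dz_pre[, , k] <- acc
    }
    out$boundary <- list(dv0 = Dm * dv_buf[[1]], da0 = p$mu * da_buf[[1]],
                         gy0 = gy0, dz_pre = dz_pre)
  }
  out
}

.state_slice <- function(state, b) {
  out <- state
  for (nm in c("v", "a", "A", "z", "refrac_count", "v_b", "can_spike")) {
    if (!is.null(out[[nm]]) && is.matrix(out[[nm]]))
      out[[nm]] <- out[[nm]][b, , drop = FALSE]
  }
  out
}

.filt_slice <- function(fs, b) {
  if (is.null(fs)) return(NULL)
  list(aL = fs$aL[b, , drop = FALSE], aS = fs$aS[b, , drop = FALSE])
}

# ---- backward ---------------------------------------------------------------

# Full outer-loop backward pass. g_y2: batch x n_out x T2 gradient on the
# phase-2 readout; reg gradients are supplied per network/phase. The
# eligibility factor of the inner update is treated as a constant of the
# phase-1 rollout (stop-gradient); the learning-signal factor is
# differentiated exactly, which routes credit through the teacher and,
# via the teacher's inputs, into the learner's phase-1 dynamics.
.meta_backward <- function(nets, fwd, cfg, g_y2, rg_h, rg_p) {
  hs <- nets$hsnn; ps <- nets$psnn
  batch <- fwd$batch
  B <- batch$B; T1 <- batch$T1; T2 <- batch$T2
  N <- hs$n_rec; d <- hs$params$d
  # phase-2 backward (batched, per-episode weight deltas)
  bp2 <- .phase2_backward(fwd$ro_h2, hs, fwd$dW, g_y = g_y2,
                          g_z = rg_h$g_z2, g_v = rg_h$g_v2,
                          g_A = rg_h$g_A2, return_boundary = fwd$carry)
  gh <- bp2$grads
  bnd <- bp2$boundary
  # gradient on the inner update (same blocks as the base weights)
  dM <- array(0, c(B, N, nets$n_input + N))
  for (b in seq_len(B))
    dM[b, , ] <- -cfg$eta_inner *
      t(rbind(bp2$ddW[[b]]$W_in, bp2$ddW[[b]]$W_rec))
  # learning-signal gradient: dLS[b,j,t] = sum_p dM[b,j,p] * e_t[b,j,p]
  dLS <- array(0, c(B, N, T1))
  if (cfg$eta_inner != 0) {
    dLS <- .inner_eligibility_scan(hs$params, hs$beta, fwd$ro_h1$psi,
                                   batch$X1, fwd$ro_h1$z, dM = dM)
  }
  # teacher backward (learning signals are its readout)
  bp_p <- surrogate_bptt(fwd$ro_p, ps, g_y = dLS,
                         g_z = rg_p$g_z, g_v = rg_p$g_v, g_A = rg_p$g_A,
                         return_dx = TRUE)
  gp <- bp_p$grads[c("W_in", "W_rec", "W_out", "b_out")]
  # learner phase-1 backward: teacher-input credit + boundary stitching
  g_z1 <- rg_h$g_z1
  if (is.null(g_z1)) g_z1 <- array(0, c(B, N, T1))
  if (T1 > 1)
    g_z1[, , 1:(T1 - 1)] <- g_z1[, , 1:(T1 - 1)] +
      bp_p$dx[, seq_len(N), 2:T1]
  g_v1 <- rg_h$g_v1; g_A1 <- rg_h$g_A1
  g_y1 <- NULL
  da_final <- NULL
  if (fwd$carry) {
    if (is.null(g_v1)) g_v1 <- array(0, c(B, N, T1))
    g_v1[, , T1] <- g_v1[, , T1] + bnd$dv0
    for (k in seq_len(d))
      g_z1[, , T1 - k + 1] <- g_z1[, , T1 - k + 1] + bnd$dz_pre[, , k]
    g_y1 <- array(0, c(B, nets$n_out, T1))
    g_y1[, , T1] <- bnd$gy0
    da_final <- bnd$da0
  }
  bp_h1 <- surrogate_bptt(fwd$ro_h1, hs, g_y = g_y1, g_z = g_z1,
                          g_v = g_v1, g_A = g_A1, da_final = da_final)
  for (nm in c("W_in", "W_rec", "W_out", "b_out"))
    gh[[nm]] <- gh[[nm]] + bp_h1$grads[[nm]]
  diag(gh$W_rec) <- 0
  list(hsnn = gh, psnn = gp)
}

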