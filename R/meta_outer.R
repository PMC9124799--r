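# Outer-loop loss assembly and training for the learning-to-learn system.

# Matching episodes: mixture-correntropy + two-phase cross-entropy on the
# sigmoid of the readout sampled at the end of each query item.
.matching_loss <- function(fwd, lam, cfg) {
  batch <- fwd$batch
  B <- batch$B
  s <- fwd$scores # B x n_way
  l <- batch$labels
  L1 <- as.numeric(mmcc_loss(as.vector(l), as.vector(s), cfg$correntropy))
  eps <- 1e-12
  L2 <- mean(rowSums(-l * log(pmax(s, eps)) -
                       (1 - l) * log(pmax(1 - s, eps))))
  g_y2 <- array(0, c(B, dim(fwd$y2)[2], batch$T2))
  g_s <- lam[2]^2 * (s - l) / B # BCE + sigmoid collapse
  if (lam[1] != 0) {
    l1g <- mmcc_loss(as.vector(l), as.vector(s), cfg$correntropy,
                     gradient = TRUE)
    g_s <- g_s + lam[1]^2 * matrix(attr(l1g, "gradient"), B) * s * (1 - s)
  }
  for (n in seq_along(batch$sample_steps))
    g_y2[, 1, batch$sample_steps[n]] <- g_s[, n]
  list(L1 = L1, L2 = L2, g_y2 = g_y2)
}

# Motor episodes: mixture-correntropy + mean squared error on the
# test-trial angular-velocity commands against the target's implied
# velocities.
.motor_loss <- function(fwd, lam, cfg) {
  batch <- fwd$batch
  B <- batch$B; T2 <- batch$T2
  err <- fwd$y2 - batch$omega
  L2 <- mean(err^2)
  xm <- matrix(aperm(batch$omega, c(1, 3, 2)), B * T2, 2)
  ym <- matrix(aperm(fwd$y2, c(1, 3, 2)), B * T2, 2)
  l1g <- mmcc_loss(xm, ym, cfg$correntropy, gradient = TRUE)
  L1 <- as.numeric(l1g)
  g_flat <- lam[1]^2 * attr(l1g, "gradient") +
    lam[2]^2 * 2 * matrix(aperm(err, c(1, 3, 2)), B * T2, 2) / length(err)
  g_y2 <- aperm(array(g_flat, c(B, T2, 2)), c(1, 3, 2))
  list(L1 = L1, L2 = L2, g_y2 = g_y2)
}

# Regularizer losses and direct gradients for both networks across both
# phases. The learner's rate is measured over the full episode. Like the
# voltage penalty, the rate loss is normalized by batch x time so that its
# gradient scale is commensurate with the task losses (see the vignette).
.meta_reg <- function(fwd, nets, lam, cfg) {
  dt <- nets$hsnn$params$dt
  batch <- fwd$batch
  B <- batch$B; T1 <- batch$T1; T2 <- batch$T2
  N <- nets$hsnn$n_rec
  reg <- cfg$regularizer
  counts_h <- apply(fwd$ro_h1$z, 2, sum) + apply(fwd$z2, 2, sum)
  Ttot <- T1 + T2
  f_h <- counts_h / (B * Ttot * dt / 1000)
  nrm_h <- B * Ttot
  L3_h <- reg$lam_f * sum((f_h - reg$f_target)^2) / nrm_h
  rg_h <- list(g_z1 = NULL, g_z2 = NULL, g_v1 = NULL, g_A1 = NULL,
               g_v2 = NULL, g_A2 = NULL)
  if (lam[3] != 0) {
    gf <- lam[3]^2 * reg$lam_f * 2 * (f_h - reg$f_target) /
      (B * Ttot * dt / 1000) / nrm_h
    rg_h$g_z1 <- array(rep(gf, each = B), c(B, N, T1))
    rg_h$g_z2 <- array(rep(gf, each = B), c(B, N, T2))
  }
  nt <- B * Ttot
  v2 <- fwd$ro_h2$v
  A2 <- fwd$ro_h2$A
  over1 <- pmax(fwd$ro_h1$v - fwd$ro_h1$A, 0)
  under1 <- pmax(-fwd$ro_h1$v - reg$v_th, 0)
  over2 <- pmax(v2 - A2, 0)
  under2 <- pmax(-v2 - reg$v_th, 0)
  L4_h <- reg$lam_v / nt * (sum(over1^2) + sum(under1^2) +
                              sum(over2^2) + sum(under2^2))
  if (lam[4] != 0) {
    cc <- lam[4]^2 * reg$lam_v / nt
    rg_h$g_v1 <- cc * (2 * over1 - 2 * under1)
    rg_h$g_A1 <- cc * (-2 * over1)
    rg_h$g_v2 <- cc * (2 * over2 - 2 * under2)
    rg_h$g_A2 <- cc * (-2 * over2)
  }
  # teacher: phase 1 only
  regp <- cfg$regularizer_psnn
  rp <- rate_regularizer(fwd$ro_p$z, regp, dt = dt)
  nrm_p <- B * T1
  L3_p <- as.numeric(rp) / nrm_p
  rg_p <- list(g_z = NULL, g_v = NULL, g_A = NULL)
  if (lam[3] != 0) {
    gfp <- lam[3]^2 * regp$lam_f * 2 * (attr(rp, "rates") - regp$f_target) /
      (B * T1 * dt / 1000) / nrm_p
    rg_p$g_z <- array(rep(gfp, each = B), c(B, nets$psnn$n_rec, T1))
  }
  overp <- pmax(fwd$ro_p$v - fwd$ro_p$A, 0)
  underp <- pmax(-fwd$ro_p$v - regp$v_th, 0)
  L4_p <- regp$lam_v / (B * T1) * (sum(overp^2) + sum(underp^2))
  if (lam[4] != 0) {
    ccp <- lam[4]^2 * regp$lam_v / (B * T1)
    rg_p$g_v <- ccp * (2 * overp - 2 * underp)
    rg_p$g_A <- ccp * (-2 * overp)
  }
  list(L3 = L3_h + L3_p, L4 = L4_h + L4_p, rg_h = rg_h, rg_p = rg_p,
       mean_rate_h = mean(f_h))
}

#' Outer-loop (learning-to-learn) training
#'
#' Meta-trains the learner/teacher pair: each iteration draws a fresh batch
#' of episodes from the task family, runs the two-phase inner trial
#' (including the teacher-driven weight update at the phase boundary),
#' evaluates the ensemble loss on the phase-2 output, and backpropagates
#' it through the full rollout — through the inner update into the
#' teacher's learning-signal pathway — updating all weights by Adam and
#' the ensemble weights by gradient descent. Deterministic given the seed.
#'
#' @param nets A [meta_networks()].
#' @param sampler A function `(n, seed)` returning a list of `n` episodes
#'   (matching) or motor tasks; see [pattern_episode_sampler()] and
#'   [motor_task_sampler()].
#' @param cfg A [meta_config()].
#' @param n_iters Outer iterations (0 returns the untrained networks).
#' @param batch_size Episodes per outer iteration.
#' @param seed Integer seed.
#' @param log_every Record a log row every this many iterations.
#' @return An object of class `meta_training`: trained `nets`, final
#'   ensemble weights `lam`, and a per-iteration `log` (losses, weights,
#'   penalty, total, accuracy or MSE, learner mean rate).
#' @export
run_outer_loop <- function(nets, sampler, cfg = meta_config(),
                           n_iters = 100, batch_size = 16, seed = 1L,
                           log_every = 1L) {
  set.seed(as.integer(seed))
  lam <- cfg$ensemble$lam
  par_names_h <- c("W_in", "W_rec", "W_out", "b_out")
  pars <- c(stats::setNames(nets$hsnn$weights[par_names_h],
                            paste0("h_", par_names_h)),
            stats::setNames(nets$psnn$weights[par_names_h],
                            paste0("p_", par_names_h)))
  opt <- adam_init(pars)
  log <- vector("list", n_iters)
  for (it in seq_len(n_iters)) {
    eps_seed <- sample.int(2^30, 1)
    episodes <- sampler(batch_size, eps_seed)
    fwd <- run_inner_trial(nets, episodes, cfg)
    task_loss <- if (nets$task == "matching") .matching_loss(fwd, lam, cfg)
                 else .motor_loss(fwd, lam, cfg)
    rg <- .meta_reg(fwd, nets, lam, cfg)
    base <- c(task_loss$L1, task_loss$L2, rg$L3, rg$L4)
    ecfg <- cfg$ensemble; ecfg$lam <- lam
    bd <- ensemble_objective(base, ecfg)
    if (!is.finite(bd$total))
      stop(sprintf("outer loop diverged (non-finite loss) at iteration %d", it))
    gr <- .meta_backward(nets, fwd, cfg, task_loss$g_y2, rg$rg_h, rg$rg_p)
    grads <- c(stats::setNames(gr$hsnn[par_names_h],
                               paste0("h_", par_names_h)),
               stats::setNames(gr$psnn[par_names_h],
                               paste0("p_", par_names_h)))
    grads <- clip_gradients(grads, cfg$grad_clip)
    upd <- adam_step(opt, pars, grads, cfg$lr_w)
    pars <- upd$params; opt <- upd$opt
    for (nm in par_names_h) {
      nets$hsnn$weights[[nm]] <- pars[[paste0("h_", nm)]]
      nets$psnn$weights[[nm]] <- pars[[paste0("p_", nm)]]
    }
    diag(nets$hsnn$weights$W_rec) <- 0
    diag(nets$psnn$weights$W_rec) <- 0
    if (cfg$ensemble$trainable) {
      lam <- update_ensemble_weights(lam, base, ecfg$eta1, ecfg$eta2,
                                     cfg$lr_lam, clip = cfg$lam_grad_clip)
    }
    if (it %% log_every == 0 || it == n_iters) {
      perf <- if (nets$task == "matching") {
        mean(fwd$decision == fwd$batch$match)
      } else {
        mean(vapply(seq_along(episodes), function(b)
          trajectory_mse(fwd$trajectories[[b]],
                         episodes[[b]]$target_trajectory), numeric(1)))
      }
      log[[it]] <- data.frame(iteration = it, L1 = base[1], L2 = base[2],
                              L3 = base[3], L4 = base[4],
                              lam1 = lam[1], lam2 = lam[2],
                              lam3 = lam[3], lam4 = lam[4],
                              penalty = bd$penalty, total = bd$total,
                              performance = perf,
                              mean_rate_hz = rg$mean_rate_h)
    }
  }
  structure(list(nets = nets, lam = lam,
                 log = do.call(rbind, log[!vapply(log, is.null, logical(1))]),
                 cfg = cfg, seed = as.integer(seed)),
            class = "meta_training")
}

#' @export
print.meta_training <- function(x, ...) {
  n <- nrow(x$log)
  cat(sprintf("meta_training: %d logged iterations; final total %.4g, performance %.3f\n",
              n, x$log$total[n], x$log$performance[n]))
  invisible(x)
}

#' Episode samplers for outer-loop training
#'
#' `pattern_episode_sampler` draws N-way matching episodes from a spike
#' pattern dataset; `motor_task_sampler` draws random reachable arm
#' movements. Both return a function `(n, seed)` producing a reproducible
#' list of episodes.
#'
#' @param dataset A `spike_pattern_dataset` with instances.
#' @param n_way,k_shot Episode shape.
#' @param noise Optional [noise_spec()] applied to episode items.
#' @return A function `(n, seed)`.
#' @export
pattern_episode_sampler <- function(dataset, n_way = 5, k_shot = 1,
                                    noise = NULL, support_repeats = 1L) {
  force(dataset); force(n_way); force(k_shot); force(noise)
  force(support_repeats)
  function(n, seed) {
    lapply(seq_len(n), function(i)
      build_episode(dataset, n_way = n_way, k_shot = k_shot, noise = noise,
                    support_repeats = support_repeats, seed = seed + i - 1L))
  }
}

#' @rdname pattern_episode_sampler
#' @param duration_ms,n_clock_channels,... Passed to
#'   [generate_motor_task()].
#' @export
motor_task_sampler <- function(duration_ms = 500, n_clock_channels = 20,
                               ...) {
  args <- list(...)
  function(n, seed) {
    lapply(seq_len(n), function(i)
      do.call(generate_motor_task,
              c(list(duration_ms = duration_ms,
                     n_clock_channels = n_clock_channels,
                     seed = seed + i - 1L), args)))
  }
}

#' Match scores of episodes under a model
#'
#' Generic used by [evaluate_fewshot()]: returns an `n_episodes x n_way`
#' matrix of match scores (higher = more likely the matching query).
#' Methods can be added for reference or oracle models.
#'
#' @param model The scoring model.
#' @param episodes List of `fewshot_episode` objects.
#' @param cfg Configuration passed to the model.
#' @return Numeric score matrix.
#' @export
episode_scores <- function(model, episodes, cfg = meta_config()) {
  UseMethod("episode_scores")
}

#' @export
episode_scores.meta_networks <- function(model, episodes,
                                         cfg = meta_config()) {
  chunks <- split(seq_along(episodes),
                  ceiling(seq_along(episodes) / 16))
  do.call(rbind, lapply(chunks, function(ix) {
    run_inner_trial(model, episodes[ix], cfg)$scores
  }))
}

#' Evaluate few-shot matching accuracy
#'
#' Runs each episode through the model and scores the phase-2 decision:
#' the query with the highest match score (sigmoid of the readout at the
#' end of its presentation; ties break to the lowest index) is compared
#' with the true match.
#'
#' @param model A [meta_networks()] (or any object with an
#'   [episode_scores()] method).
#' @param episodes List of `fewshot_episode` objects.
#' @param cfg A [meta_config()].
#' @return List with `accuracy`, per-episode `correct`, `decisions`, and
#'   `n_episodes`.
#' @export
evaluate_fewshot <- function(model, episodes, cfg = meta_config()) {
  scores <- episode_scores(model, episodes, cfg)
  decisions <- max.col(scores, ties.method = "first")
  truth <- vapply(episodes, `[[`, integer(1), "match")
  list(accuracy = mean(decisions == truth), correct = decisions == truth,
       decisions = decisions, n_episodes = length(episodes))
}

#' Evaluate one-shot motor learning
#'
#' For each arm task, runs the two-trial episode twice — without and with
#' the phase-boundary weight update — and reports the test-trial
#' trajectory mean squared error in both conditions.
#'
#' @param nets A [meta_networks()] built for the motor task.
#' @param tasks List of [generate_motor_task()] objects.
#' @param cfg A [meta_config()].
#' @return Data frame with columns `task`, `mse_pre`, `mse_post`.
#' @export
evaluate_motor <- function(nets, tasks, cfg = meta_config()) {
  res <- lapply(seq_along(tasks), function(i) {
    pre <- run_inner_trial(nets, tasks[i], cfg, inner_update = FALSE)
    post <- run_inner_trial(nets, tasks[i], cfg, inner_update = TRUE)
    data.frame(
      task = i,
      mse_pre = trajectory_mse(pre$trajectories[[1]],
                               tasks[[i]]$target_trajectory),
      mse_post = trajectory_mse(post$trajectories[[1]],
                                tasks[[i]]$target_trajectory))
  })
  do.call(rbind, res)
}
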