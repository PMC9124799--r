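# Small learner/teacher system shared across tests.
toy_meta <- function(task = "matching", n_pat = 10, seed = 3, gain = 2) {
  if (task == "matching") {
    meta_networks(n_input = n_pat + 1, n_out = 1, n_extra_psnn = 2,
                  n_tlif = 4, n_lif = 6, n_psnn = 6, task = "matching",
                  gain = gain, seed = seed)
  } else {
    meta_networks(n_input = 8, n_out = 2, n_extra_psnn = 3,
                  n_tlif = 4, n_lif = 6, n_psnn = 6, task = "motor",
                  gain = gain, seed = seed)
  }
}

toy_pattern_ds <- function(n_classes = 6, n_pat = 10, dur = 15, seed = 5) {
  ds <- generate_templates(n_classes, n_neurons = n_pat, duration_ms = dur,
                           seed = seed)
  instantiate_poisson_noise(ds, sigma_noise = 2, n_instances = 5,
                            seed = seed + 1L)
}

test_that("convolutional encoder has the documented geometry", {
  vnn <- vnn_init(seed = 2)
  f <- conv_encode(matrix(0, 28, 28), vnn)
  expect_length(f, 64 * 3 * 3) # three conv/pool blocks: 28 -> 14 -> 7 -> 3
  expect_equal(f, rep(0, 576)) # zero image, zero biases -> zero features
  set.seed(1)
  img <- matrix(runif(28 * 28), 28)
  f1 <- conv_encode(img, vnn)
  expect_identical(f1, conv_encode(img, vnn)) # inference mode: deterministic
  expect_gt(sum(f1 != 0), 0)
  expect_error(conv_encode(matrix(0, 20, 20), vnn), "28 x 28")
})

test_that("learning signals exist only in phase 1 and obey causal isolation", {
  nets <- toy_meta()
  ds <- toy_pattern_ds()
  cfg <- meta_config(eta_inner = 0.05)
  eps <- pattern_episode_sampler(ds, 3, 1)(2, 7)
  fwd <- run_inner_trial(nets, eps, cfg)
  expect_equal(fwd$LS_phase2, array(0, dim(fwd$LS_phase2)))
  expect_gt(max(abs(fwd$LS)), 0)
  # zeroing the teacher-to-learner pathway removes any effect of the
  # teacher (and everything it sees) on phase-2 outputs
  nets0 <- nets
  nets0$psnn$weights$W_out[] <- 0
  nets0$psnn$weights$b_out[] <- 0
  fwd0 <- run_inner_trial(nets0, eps, cfg)
  nets0b <- nets0
  nets0b$psnn$weights$W_in[] <- 2 * nets0b$psnn$weights$W_in # perturb teacher
  fwd0b <- run_inner_trial(nets0b, eps, cfg)
  expect_identical(fwd0$y2, fwd0b$y2)
  # and phase-2 behavior equals an episode with no inner update at all
  fwd_no <- run_inner_trial(nets0, eps, cfg, inner_update = FALSE)
  expect_identical(fwd0$y2, fwd_no$y2)
})

test_that("optimized meta pathways match a naive per-episode reference", {
  set.seed(1)
  nets <- toy_meta()
  ds <- toy_pattern_ds()
  cfg <- meta_config(eta_inner = 0.05)
  eps_list <- pattern_episode_sampler(ds, 3, 1)(3, 11)
  lam <- c(0.5, 0.5, 0.5, 0.5)
  fwd <- run_inner_trial(nets, eps_list, cfg)
  tl <- snnfewshot:::.matching_loss(fwd, lam, cfg)
  rg <- snnfewshot:::.meta_reg(fwd, nets, lam, cfg)
  hs <- nets$hsnn
  B <- 3; T1 <- fwd$batch$T1
  N <- hs$n_rec; n_in <- nets$n_input; P <- n_in + N
  p <- hs$params; d <- p$d
  # naive eligibility slabs, elementwise
  zb_in <- matrix(0, B, n_in); zb_rec <- matrix(0, B, N)
  hist <- vector("list", T1)
  E_a <- array(0, c(B, N, P))
  psi_prev <- matrix(0, B, N); zlag_prev <- matrix(0, B, P)
  slabs <- vector("list", T1)
  for (t in 1:T1) {
    zb_in <- p$alpha * zb_in + matrix(fwd$batch$X1[, , t], B)
    zb_rec <- p$alpha * zb_rec + matrix(fwd$ro_h1$z[, , t], B)
    hist[[t]] <- zb_rec
    zlag <- cbind(zb_in, if (t > d) hist[[t - d]] else matrix(0, B, N))
    psi_t <- matrix(fwd$ro_h1$psi[, , t], B)
    if (t > 1) {
      for (b in 1:B) for (n in 1:N)
        E_a[b, n, ] <- (p$rho - hs$beta[n] * psi_prev[b, n]) * E_a[b, n, ] +
          psi_prev[b, n] * zlag_prev[b, ]
    }
    e_t <- array(0, c(B, N, P))
    for (b in 1:B) for (n in 1:N)
      e_t[b, n, ] <- psi_t[b, n] * (zlag[b, ] - hs$beta[n] * E_a[b, n, ])
    slabs[[t]] <- e_t
    psi_prev <- psi_t; zlag_prev <- zlag
  }
  Mref <- array(0, c(B, N, P))
  for (t in 1:T1)
    Mref <- Mref + array(matrix(fwd$LS[, , t], B), c(B, N, P)) * slabs[[t]]
  Mfast <- snnfewshot:::.inner_eligibility_scan(p, hs$beta, fwd$ro_h1$psi,
                                                fwd$batch$X1, fwd$ro_h1$z,
                                                LS = fwd$LS)
  expect_equal(Mfast, Mref, tolerance = 1e-12)
  # per-episode simulate/backprop reference for phase 2
  gh_ref <- lapply(hs$weights[c("W_in", "W_rec", "W_out", "b_out")],
                   function(m) { m[] <- 0; m })
  dM_ref <- array(0, c(B, N, P))
  for (b in 1:B) {
    net_b <- hs
    net_b$weights$W_in <- hs$weights$W_in + fwd$dW[[b]]$W_in
    net_b$weights$W_rec <- hs$weights$W_rec + fwd$dW[[b]]$W_rec
    st_b <- snnfewshot:::.state_slice(fwd$ro_h1$state, b)
    z_pre <- array(0, c(1, N, d))
    for (k in 1:d) z_pre[1, , k] <- fwd$ro_h1$z[b, , T1 - k + 1]
    ro <- simulate_network(net_b, fwd$batch$X2[b, , , drop = FALSE],
                           state0 = st_b,
                           y0 = matrix(fwd$ro_h1$y[b, , T1], 1, 1),
                           z_pre = z_pre,
                           filt0 = snnfewshot:::.filt_slice(fwd$ro_h1$filt_state, b))
    expect_equal(ro$z[1, , ], fwd$z2[b, , ]) # batched forward agrees
    expect_equal(ro$y[1, 1, ], fwd$y2[b, 1, ])
    bp <- surrogate_bptt(ro, net_b, g_y = tl$g_y2[b, , , drop = FALSE],
                         g_z = rg$rg_h$g_z2[b, , , drop = FALSE],
                         g_v = rg$rg_h$g_v2[b, , , drop = FALSE],
                         g_A = rg$rg_h$g_A2[b, , , drop = FALSE])
    for (nm in names(gh_ref)) gh_ref[[nm]] <- gh_ref[[nm]] + bp$grads[[nm]]
    dM_ref[b, , ] <- -cfg$eta_inner * t(rbind(bp$grads$W_in, bp$grads$W_rec))
  }
  bp2 <- snnfewshot:::.phase2_backward(fwd$ro_h2, hs, fwd$dW, g_y = tl$g_y2,
                                       g_z = rg$rg_h$g_z2,
                                       g_v = rg$rg_h$g_v2,
                                       g_A = rg$rg_h$g_A2)
  for (nm in names(gh_ref))
    expect_equal(bp2$grads[[nm]], gh_ref[[nm]], tolerance = 1e-10)
  dM_fast <- array(0, c(B, N, P))
  for (b in 1:B)
    dM_fast[b, , ] <- -cfg$eta_inner *
      t(rbind(bp2$ddW[[b]]$W_in, bp2$ddW[[b]]$W_rec))
  expect_equal(dM_fast, dM_ref, tolerance = 1e-10)
  # dLS against the slab definition
  dLS_ref <- array(0, c(B, N, T1))
  for (t in 1:T1) dLS_ref[, , t] <- rowSums(dM_ref * slabs[[t]], dims = 2)
  dLS_fast <- snnfewshot:::.inner_eligibility_scan(p, hs$beta,
                                                   fwd$ro_h1$psi,
                                                   fwd$batch$X1,
                                                   fwd$ro_h1$z, dM = dM_fast)
  expect_equal(dLS_fast, dLS_ref, tolerance = 1e-10)
})

test_that("meta gradients on spike-free pathways match finite differences", {
  set.seed(1)
  nets <- toy_meta()
  ds <- toy_pattern_ds()
  cfg <- meta_config(eta_inner = 0.05)
  eps_list <- pattern_episode_sampler(ds, 3, 1)(3, 11)
  lam <- c(0.5, 0.5, 0.5, 0.5)
  total_loss <- function(nets) {
    fwd <- run_inner_trial(nets, eps_list, cfg)
    tl <- snnfewshot:::.matching_loss(fwd, lam, cfg)
    rg <- snnfewshot:::.meta_reg(fwd, nets, lam, cfg)
    sum(lam^2 * c(tl$L1, tl$L2, rg$L3, rg$L4))
  }
  fwd <- run_inner_trial(nets, eps_list, cfg)
  tl <- snnfewshot:::.matching_loss(fwd, lam, cfg)
  rg <- snnfewshot:::.meta_reg(fwd, nets, lam, cfg)
  gr <- snnfewshot:::.meta_backward(nets, fwd, cfg, tl$g_y2, rg$rg_h,
                                    rg$rg_p)
  eps <- 1e-5
  # learner readout: the only parameter -> loss path with no spike inside
  ih <- which(abs(gr$hsnn$W_out) == max(abs(gr$hsnn$W_out)), arr.ind = TRUE)[1, ]
  np <- nets; np$hsnn$weights$W_out[ih[1], ih[2]] <-
    np$hsnn$weights$W_out[ih[1], ih[2]] + eps
  nm <- nets; nm$hsnn$weights$W_out[ih[1], ih[2]] <-
    nm$hsnn$weights$W_out[ih[1], ih[2]] - eps
  fd <- (total_loss(np) - total_loss(nm)) / (2 * eps)
  expect_equal(gr$hsnn$W_out[ih[1], ih[2]], fd, tolerance = 1e-4)
})

test_that("matching accuracy evaluation supports oracle and random models", {
  ds <- toy_pattern_ds(n_classes = 8)
  eps <- pattern_episode_sampler(ds, 4, 1)(40, 5)
  # an oracle that reads the ground truth scores every episode correctly
  oracle <- structure(list(), class = "oracle_model")
  registerS3method("episode_scores", "oracle_model",
                   function(model, episodes, cfg = NULL) {
                     t(vapply(episodes, function(e) as.numeric(e$labels),
                              numeric(episodes[[1]]$n_way)))
                   },
                   envir = asNamespace("snnfewshot"))
  ev <- evaluate_fewshot(oracle, eps)
  expect_equal(ev$accuracy, 1)
  # an untrained network scores near chance over many episodes
  nets <- toy_meta()
  eps2 <- pattern_episode_sampler(ds, 4, 1)(200, 6)
  ev2 <- evaluate_fewshot(nets, eps2, meta_config())
  expect_lt(abs(ev2$accuracy - 0.25), 3 * sqrt(0.25 * 0.75 / 200))
  # accuracy is invariant to episode order
  perm <- sample(seq_along(eps2))
  ev3 <- evaluate_fewshot(nets, eps2[perm], meta_config())
  expect_equal(ev3$accuracy, ev2$accuracy)
  expect_equal(ev3$correct, ev2$correct[perm], ignore_attr = TRUE)
})

test_that("motor episodes run both trials and integrate trajectories", {
  nets <- toy_meta("motor")
  cfg <- meta_config(eta_inner = 0.05)
  tasks <- motor_task_sampler(60, 8)(2, 9)
  fwd <- run_inner_trial(nets, tasks, cfg)
  expect_length(fwd$trajectories, 2)
  expect_equal(dim(fwd$trajectories[[1]]), c(60, 2))
  ev <- evaluate_motor(nets, tasks, cfg)
  expect_equal(nrow(ev), 2)
  expect_true(all(is.finite(c(ev$mse_pre, ev$mse_post))))
  # outer loop smoke: runs, logs, reproducible
  fit <- run_outer_loop(nets, motor_task_sampler(60, 8), cfg,
                        n_iters = 3, batch_size = 2, seed = 12)
  fit2 <- run_outer_loop(nets, motor_task_sampler(60, 8), cfg,
                         n_iters = 3, batch_size = 2, seed = 12)
  expect_identical(fit$log, fit2$log)
  expect_equal(nrow(fit$log), 3)
})

test_that("the outer loop with zero iterations returns the untrained system", {
  nets <- toy_meta()
  ds <- toy_pattern_ds()
  fit <- run_outer_loop(nets, pattern_episode_sampler(ds, 3, 1),
                        meta_config(), n_iters = 0, batch_size = 2, seed = 4)
  expect_identical(fit$nets$hsnn$weights$W_in, nets$hsnn$weights$W_in)
  expect_identical(fit$nets$psnn$weights$W_out, nets$psnn$weights$W_out)
})
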