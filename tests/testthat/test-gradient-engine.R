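test_that("low-pass filtered spikes equal the explicit geometric sum", {
  expect_equal(low_pass_spikes(matrix(0, 3, 10), 0.7), matrix(0, 3, 10))
  z <- matrix(0, 1, 12); z[1, 4] <- 1
  zb <- low_pass_spikes(z, 0.6)
  expect_equal(zb[1, 4:12], 0.6^(0:8))
  # alpha = 0 degenerates to the raster itself
  set.seed(1)
  zr <- matrix(rbinom(40, 1, 0.4), 4, 10)
  expect_equal(low_pass_spikes(zr, 0), zr)
  # recursion equals the explicit double sum on random input
  a <- 0.83
  zb2 <- low_pass_spikes(zr, a)
  for (t in c(1, 5, 10))
    expect_equal(zb2[, t],
                 as.numeric(zr[, 1:t, drop = FALSE] %*% a^(t - (1:t))))
})

test_that("LIF eligibility has the outer-product structure and zeros", {
  psi <- rbind(c(0.3, 0.2, 0, 0.1), c(0, 0, 0, 0))
  zbar <- rbind(c(1, 0.8, 0.6, 0.5), c(0, 0, 0, 0))
  e <- eligibility_lif(psi, zbar, d = 1)
  # silent presynaptic neuron: trace 0 for all its synapses
  expect_equal(e[, 2, ], matrix(0, 2, 4))
  # psi = 0 postsynaptic neuron: 0
  expect_equal(e[2, , ], matrix(0, 2, 4))
  # delayed outer product elsewhere: e(t) = psi(t) * zbar(t - 1)
  expect_equal(e[1, 1, 2], 0.2 * 1)
  expect_equal(e[1, 1, 4], 0.1 * 0.6)
  expect_equal(e[1, 1, 1], 0) # no presynaptic history before the delay
})

test_that("closed-form eligibility recursions match the Jacobian-product oracle", {
  set.seed(4)
  p <- neuron_params(beta_adapt = 0.45, tau_a = 30)
  Tn <- 6
  psi <- matrix(runif(Tn, 0, 0.3), 1)
  pre_raw <- matrix(rbinom(Tn, 1, 0.6), 1)
  zbar <- low_pass_spikes(pre_raw, p$alpha)
  # package route (input synapse, no delay)
  p0 <- p; p0$d <- 0L
  el <- eligibility_alif(psi, zbar, p0, beta = 0.45)
  # independent route: explicit 2x2 Jacobian accumulation per step
  jac <- jacobian_eligibility(psi[1, ], pre_raw[1, ], p$alpha, 0.45, p$rho)
  expect_equal(as.numeric(el$e[1, 1, ]), jac$e, tolerance = 1e-12)
  # beta = 0 reduces exactly to the LIF trace
  el0 <- eligibility_alif(psi, zbar, p0, beta = 0)
  expect_equal(el0$e, eligibility_lif(psi, zbar, d = 0))
  # with delay d = 1, e at t = 1 has no history
  el1 <- eligibility_alif(psi, zbar, p, beta = 0.45)
  expect_equal(as.numeric(el1$e[, , 1]), 0)
})

test_that("BPTT equals learning-signal x eligibility without recurrence", {
  # without recurrent weights the full gradient factorizes exactly into
  # per-synapse eligibility traces times the readout learning signal
  set.seed(3)
  p <- neuron_params(t_refrac = 2, beta_adapt = 0.3)
  w <- network_weights(3, 2, 1, seed = 2, gain = 3)
  w$W_rec[] <- 0
  net <- snn_network(w, p, kind = "alif", adaptive = TRUE)
  x <- random_input(1, 3, 12, p = 0.5, seed = 3)
  ro <- simulate_network(net, x)
  expect_gt(sum(ro$z), 0)
  bp <- surrogate_bptt(ro, net, g_y = ro$y) # loss sum(y^2)/2
  Tn <- 12
  Ls <- matrix(0, 2, Tn); gacc <- matrix(0, 1, 1)
  for (t in Tn:1) {
    gacc <- p$nu * gacc + ro$y[, , t]
    Ls[, t] <- (1 - p$nu) * (gacc %*% t(w$W_out))
  }
  zbar <- low_pass_spikes(matrix(x[1, , ], 3, Tn), p$alpha)
  psi <- matrix(ro$psi[1, , ], 2, Tn)
  p0 <- p; p0$d <- 0L # input synapses carry no transmission delay
  el <- eligibility_alif(psi, zbar, p0, beta = 0.3)
  gW <- matrix(0, 2, 3)
  for (t in 1:Tn) gW <- gW + Ls[, t] * el$e[, , t]
  expect_equal(bp$grads$W_in, t(gW), tolerance = 1e-12)
})

test_that("recurrent-synapse BPTT matches eligibility on a feed-forward chain", {
  # neuron 1 (input-driven) -> neuron 2 -> readout, no feedback: the
  # learning signal for neuron 2 is purely the readout credit, so the
  # eligibility route is exact for W_rec[1, 2]
  p <- neuron_params(t_refrac = 1, beta_adapt = 0.3)
  w <- network_weights(1, 2, 1, seed = 5, gain = 1)
  w$W_in[1, ] <- c(1.4, 0)
  w$W_rec[] <- 0; w$W_rec[1, 2] <- 0.8
  w$W_out[, 1] <- c(0, 1.1)
  net <- snn_network(w, p, kind = "alif", adaptive = TRUE)
  x <- random_input(1, 1, 15, p = 0.6, seed = 6)
  ro <- simulate_network(net, x)
  expect_gt(sum(ro$z[1, 2, ]), 0)
  bp <- surrogate_bptt(ro, net, g_y = ro$y)
  Tn <- 15
  Ls <- matrix(0, 2, Tn); gacc <- matrix(0, 1, 1)
  for (t in Tn:1) {
    gacc <- p$nu * gacc + ro$y[, , t]
    Ls[, t] <- (1 - p$nu) * (gacc %*% t(w$W_out))
  }
  zbar1 <- low_pass_spikes(matrix(ro$z[1, 1, ], 1, Tn), p$alpha)
  psi2 <- matrix(ro$psi[1, 2, ], 1, Tn)
  el <- eligibility_alif(psi2, zbar1, p, beta = 0.3) # delayed presynapse
  g12 <- sum(Ls[2, ] * el$e[1, 1, ])
  expect_equal(bp$grads$W_rec[1, 2], g12, tolerance = 1e-12)
})

test_that("readout gradients match central finite differences exactly", {
  net <- toy_network(n_in = 4, n_rec = 6, n_out = 3, seed = 7, gain = 2)
  x <- random_input(4, 4, 25, seed = 42)
  ro <- simulate_network(net, x)
  bp <- surrogate_bptt(ro, net, g_y = ro$y)
  lossfun <- function(n2) { r <- simulate_network(n2, x); sum(r$y^2) / 2 }
  eps <- 1e-6
  fd <- bp$grads$W_out * 0
  for (i in seq_len(nrow(fd))) for (k in seq_len(ncol(fd))) {
    np <- net; np$weights$W_out[i, k] <- np$weights$W_out[i, k] + eps
    nm <- net; nm$weights$W_out[i, k] <- nm$weights$W_out[i, k] - eps
    fd[i, k] <- (lossfun(np) - lossfun(nm)) / (2 * eps)
  }
  expect_equal(bp$grads$W_out, fd, tolerance = 1e-5)
  fdb <- numeric(3)
  for (k in 1:3) {
    np <- net; np$weights$b_out[k] <- np$weights$b_out[k] + eps
    nm <- net; nm$weights$b_out[k] <- nm$weights$b_out[k] - eps
    fdb[k] <- (lossfun(np) - lossfun(nm)) / (2 * eps)
  }
  expect_equal(bp$grads$b_out, fdb, tolerance = 1e-5)
})

test_that("hidden-weight gradient agrees with a smoothed-model oracle", {
  # subthreshold 2-neuron, 5-step toy held close to threshold, where the
  # steep-sigmoid stand-in (matching derivative 0.3 at threshold) is an
  # accurate smooth model of the surrogate
  p <- neuron_params(t_refrac = 0, beta_adapt = 0)
  w <- network_weights(1, 2, 1, seed = 8)
  w$W_in[1, ] <- c(0.985, 0.97)
  w$W_rec[] <- 0; w$W_rec[1, 2] <- 0.005; w$W_rec[2, 1] <- 0.004
  w$W_out[, 1] <- c(0.05, 0.04)
  w$b_out <- 0.8
  net <- snn_network(w, p, kind = "lif")
  # charge in one step, then hold: v_j sits at W_in[1, j] every step
  xm <- matrix(c(1, rep(1 - p$alpha, 4)), 1, 5)
  x <- array(xm, c(1, 1, 5))
  ro <- simulate_network(net, x)
  expect_equal(sum(ro$z), 0) # stays just below threshold
  expect_gt(max(ro$psi), 0.29) # deep inside the surrogate's support
  bp <- surrogate_bptt(ro, net, g_y = ro$y)
  eps <- 1e-6
  fd <- matrix(0, 1, 2)
  for (j in 1:2) {
    wp <- w$W_in; wp[1, j] <- wp[1, j] + eps
    wm <- w$W_in; wm[1, j] <- wm[1, j] - eps
    fd[1, j] <- (smooth_model_loss(wp, w$W_rec, w$W_out, w$b_out, xm, p,
                                   k = 2) -
                   smooth_model_loss(wm, w$W_rec, w$W_out, w$b_out, xm, p,
                                     k = 2)) / (2 * eps)
  }
  expect_equal(bp$grads$W_in, fd, tolerance = 0.1)
})

test_that("Adam behaves as documented at its fixed points and first step", {
  pars <- list(a = matrix(c(1, 2), 1), b = 0.5)
  opt <- adam_init(pars)
  upd <- adam_step(opt, pars, list(a = matrix(0, 1, 2), b = 0), lr = 0.1)
  expect_equal(upd$params, pars) # zero gradient: unchanged
  g <- list(a = matrix(c(0.3, -2), 1), b = 5)
  u1 <- adam_step(opt, pars, g, lr = 0.1)
  # first bias-corrected step is a sign step of magnitude ~ lr
  expect_equal(u1$params$a, pars$a - 0.1 * sign(g$a), tolerance = 1e-6)
  u1b <- adam_step(opt, pars, g, lr = 0.1)
  expect_identical(u1, u1b) # deterministic
})

test_that("ensemble-weight descent has the documented fixed points and descent", {
  # lam_j = 0 is a fixed point of its own coordinate
  lam <- c(0, 0.5, 0.5, 0.5)
  l2 <- update_ensemble_weights(lam, c(1, 1, 1, 1), 0.1, 10, lr = 1e-2)
  expect_equal(l2[1], 0)
  # equal losses with sum lam^2 > 1: the norm strictly decreases
  lam3 <- rep(0.8, 4)
  l3 <- update_ensemble_weights(lam3, rep(2, 4), 0.1, 10, lr = 1e-3)
  expect_lt(sum(l3^2), sum(lam3^2))
  # with a dominant quadratic penalty the constraint is met to 1e-2
  set.seed(9)
  lam4 <- runif(4); lam4 <- lam4 / sqrt(sum(lam4^2))
  for (i in 1:2000)
    lam4 <- update_ensemble_weights(lam4, c(1, 2, 3, 4), 0.1, 200, lr = 1e-3)
  expect_lt(abs(sum(lam4^2) - 1), 1e-2)
})

test_that("training reduces the loss and is reproducible", {
  ds <- generate_templates(4, n_neurons = 15, duration_ms = 40, seed = 31)
  ds <- instantiate_poisson_noise(ds, sigma_noise = 2, n_instances = 6,
                                  seed = 32)
  p <- neuron_params()
  net <- snn_network(network_weights(15, 12, 4, seed = 33, gain = 2), p,
                     kind = "alif", adaptive = c(rep(TRUE, 5), rep(FALSE, 7)))
  cfg <- train_config(batch_size = 8)
  fit0 <- train_network(net, ds, cfg, n_iters = 0, seed = 34)
  expect_identical(fit0$network$weights$W_in, net$weights$W_in)
  fit <- train_network(net, ds, cfg, n_iters = 40, seed = 34)
  expect_lt(utils::tail(fit$log$total, 1), fit$log$total[1])
  fit2 <- train_network(net, ds, cfg, n_iters = 40, seed = 34)
  expect_identical(fit$log, fit2$log) # bit-identical rerun
  expect_false(identical(fit$network$weights$W_in, net$weights$W_in))
})

test_that("training resumes bit-exactly from a checkpointed state", {
  ds <- generate_templates(4, n_neurons = 10, duration_ms = 30, seed = 61)
  ds <- instantiate_poisson_noise(ds, 1, 5, seed = 62)
  net <- snn_network(network_weights(10, 8, 4, seed = 63), neuron_params(),
                     kind = "lif")
  cfg <- train_config(batch_size = 4)
  full <- train_network(net, ds, cfg, n_iters = 10, seed = 64)
  half <- train_network(net, ds, cfg, n_iters = 5, seed = 64)
  rest <- train_network(NULL, ds, cfg, n_iters = 5, init = half)
  expect_identical(rest$network$weights, full$network$weights)
  joined <- rbind(half$log, rest$log)
  rownames(joined) <- NULL
  expect_equal(joined, `rownames<-`(full$log, NULL))
})
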