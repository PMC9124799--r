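test_that("membrane potential decays geometrically without input or spikes", {
  p <- params_with_alpha(0.8)
  expect_equal(p$alpha, 0.8)
  st <- neuron_state(1, 1, p$v_th)
  st$v[] <- 0.5
  w <- network_weights(1, 1, 1, seed = 1)
  w$W_rec[] <- 0
  st <- lif_step(st, matrix(0, 1, 1), p, w, matrix(0, 1, 1))
  expect_equal(as.numeric(st$v), 0.4)
  expect_equal(as.numeric(st$z), 0)
})

test_that("a spike triggers the refractory period of exactly t_refrac/dt steps", {
  p <- neuron_params(t_refrac = 5, dt = 1, beta_adapt = 0)
  w <- network_weights(1, 1, 1, seed = 1); w$W_rec[] <- 0
  st <- neuron_state(1, 1, p$v_th)
  zs <- numeric(12)
  for (t in 1:12) {
    # constant strong suprathreshold drive
    st <- lif_step(st, matrix(2, 1, 1), p, w, matrix(0, 1, 1))
    zs[t] <- st$z
  }
  first <- which(zs == 1)[1]
  expect_equal(first, 1)
  expect_equal(zs[first + 1:5], rep(0, 5)) # silenced for 5 steps
  expect_equal(zs[first + 6], 1)           # fires again right after
})

test_that("all-zero weights and input give an identically zero raster", {
  net <- toy_network(seed = 3)
  net$weights$W_in[] <- 0; net$weights$W_rec[] <- 0
  ro <- simulate_network(net, array(0, c(2, 3, 30)))
  expect_equal(sum(ro$z), 0)
  expect_equal(ro$y, array(0, dim(ro$y)))
})

test_that("adaptive threshold follows the exact recursion", {
  p <- neuron_params(tau_a = -1 / log(0.9), beta_adapt = 0.7) # mu = 0.9
  expect_equal(p$mu, 0.9)
  st <- neuron_state(1, 1, p$v_th)
  # no spikes ever: threshold stays at v_th
  for (t in 1:5) st <- alif_threshold_update(st, p)
  expect_equal(as.numeric(st$A), p$v_th)
  # single spike at t = 0, then unroll: a(3) = 0.9^2
  st <- neuron_state(1, 1, p$v_th)
  st$z[] <- 1
  st <- alif_threshold_update(st, p) # a(1) = 1
  st$z[] <- 0
  st <- alif_threshold_update(st, p) # a(2) = 0.9
  st <- alif_threshold_update(st, p) # a(3) = 0.81
  expect_equal(as.numeric(st$a), 0.81)
  expect_equal(as.numeric(st$A), 0.7 * 0.81 + p$v_th)
})

test_that("default adaptation decay matches the 200 ms constant at 1 ms steps", {
  expect_equal(neuron_params()$mu, exp(-1 / 200))
})

test_that("two-compartment soma decouples, settles, and jumps as derived", {
  p <- neuron_params(t_refrac = 0, beta_adapt = 0)
  w <- network_weights(1, 1, 1, seed = 1); w$W_rec[] <- 0
  # g_b = 0: pure exponential-Euler decay toward 0
  dp0 <- dendrite_params(g_b = 0, C_m = 10)
  st <- neuron_state(1, 1, p$v_th); st$v[] <- 0.8
  st1 <- tlif_step(st, matrix(0, 1, 1), dp0, p, w, matrix(0, 1, 1))
  expect_equal(as.numeric(st1$v), (1 - p$dt / dp0$tau) * 0.8)
  # constant dendritic drive: fixed point V* = (g_b/g_l) c / (1 + g_b/g_l)
  dp <- dendrite_params(g_b = 2, g_l = 1, C_m = 10)
  cval <- 0.3
  w2 <- w; w2$W_in[] <- 1
  st <- neuron_state(1, 1, 10) # high threshold: no spikes
  for (t in 1:400)
    st <- tlif_step(st, matrix(cval, 1, 1), dp, p, w2, matrix(0, 1, 1))
  expect_equal(as.numeric(st$v), 2 * cval / 3, tolerance = 1e-6)
  # a single delayed recurrent spike moves V by (dt/tau) * w_rec
  wr <- w; wr$W_rec <- matrix(0.5, 1, 1) # self-weight stands in for a synapse
  st <- neuron_state(1, 1, 10)
  st2 <- tlif_step(st, matrix(0, 1, 1), dp, p, wr, matrix(1, 1, 1))
  expect_equal(as.numeric(st2$v), (p$dt / dp$tau) * 0.5)
})

test_that("input response kernel is causal, zero at lag 0, and integrates to 1", {
  dp <- dendrite_params(tau_L = 10, tau_s = 2)
  expect_equal(input_response_filter(matrix(0, 2, 40), dp), matrix(0, 2, 40))
  # single spike at t = 1: response starts at 0 (kappa(0) = 0)
  x <- matrix(0, 1, 400); x[1, 1] <- 1
  dt <- 0.1 * dp$tau_s
  s <- input_response_filter(x, dp, dt = dt)
  expect_equal(s[1, 1], 0)
  expect_gt(s[1, 5], 0)
  expect_equal(sum(s) * dt, 1, tolerance = 0.01)
  expect_error(input_response_filter(x, dendrite_params(tau_L = 3, tau_s = 2.9999)),
               NA) # close constants fine; equality errors:
  dp_bad <- dendrite_params(tau_L = 10, tau_s = 2)
  dp_bad$tau_s <- 10
  expect_error(input_response_filter(x, dp_bad), "degenerate")
})

test_that("recursive readout equals the explicit leaky sum", {
  p <- neuron_params()
  set.seed(7)
  w <- network_weights(1, 6, 3, seed = 7)
  w$b_out <- c(0.2, -0.1, 0)
  z <- matrix(rbinom(6 * 50, 1, 0.3), 6, 50)
  y <- matrix(w$b_out, 1, 3)
  rec <- matrix(0, 3, 50)
  for (t in 1:50) {
    y <- readout_update(y, matrix(z[, t], 1), w, p)
    rec[, t] <- y
  }
  exp_y <- explicit_readout(z, w$W_out, w$b_out, p$nu)
  expect_equal(rec, exp_y, tolerance = 1e-10)
  # no spikes ever: y stays at the bias
  y0 <- matrix(w$b_out, 1, 3)
  expect_equal(readout_update(y0, matrix(0, 1, 6), w, p), y0)
  # single spike of neuron j at t0 decays as (1 - nu) nu^(t - t0) W_out[j, ]
  zz <- matrix(0, 6, 10); zz[2, 4] <- 1
  yy <- explicit_readout(zz, w$W_out, w$b_out, p$nu)
  expect_equal(yy[, 8], (1 - p$nu) * p$nu^4 * w$W_out[2, ] + w$b_out)
})

test_that("pseudo-derivative takes its documented values", {
  p <- neuron_params(v_th = 1.0)
  expect_equal(pseudo_derivative(1.0, params = p, kind = "lif"), 0.3)
  expect_equal(pseudo_derivative(0.0, params = p, kind = "lif"), 0.0)
  expect_equal(pseudo_derivative(0.5, params = p, kind = "lif"), 0.15)
  # adaptive form measures distance to the effective threshold
  expect_equal(pseudo_derivative(1.2, A = 1.2, params = p, kind = "alif"), 0.3)
  # refractory mask zeroes the value
  expect_equal(pseudo_derivative(1.0, params = p, kind = "lif",
                                 refractory = TRUE), 0)
})

test_that("rollouts satisfy the threshold identity and refractory contract", {
  net <- toy_network(n_in = 5, n_rec = 8, seed = 11, gain = 3)
  x <- random_input(3, 5, 60, p = 0.4, seed = 2)
  ro <- simulate_network(net, x)
  expect_gt(sum(ro$z), 0)
  # A(t) = beta * a(t) + v_th at every step: reconstruct a from spikes
  p <- net$params
  a <- matrix(0, 3, 8)
  for (t in 1:60) {
    zprev <- if (t > 1) matrix(ro$z[, , t - 1], 3) else matrix(0, 3, 8)
    a <- p$mu * a + zprev
    expect_equal(matrix(ro$A[, , t], 3),
                 sweep(a, 2, net$beta, `*`) + p$v_th)
  }
  # after every spike, z = 0 for exactly n_refrac steps
  for (b in 1:3) for (j in 1:8) {
    zs <- ro$z[b, j, ]
    for (t in which(zs == 1)) {
      win <- zs[seq(t + 1, min(t + p$n_refrac, 60))]
      expect_equal(sum(win), 0)
    }
  }
})

test_that("stronger adaptation never increases the spike count", {
  x <- random_input(2, 5, 80, p = 0.5, seed = 5)
  counts <- sapply(c(0, 0.2, 0.5, 1.0), function(b) {
    p <- neuron_params(beta_adapt = b)
    w <- network_weights(5, 6, 1, seed = 9, gain = 3)
    net <- snn_network(w, p, kind = "alif", adaptive = TRUE)
    sum(simulate_network(net, x)$z)
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("zero adaptation impact reproduces plain LIF bit for bit", {
  x <- random_input(2, 4, 50, p = 0.4, seed = 8)
  p <- neuron_params(beta_adapt = 0)
  w <- network_weights(4, 5, 2, seed = 4, gain = 3)
  ro_alif <- simulate_network(snn_network(w, p, kind = "alif", adaptive = TRUE), x)
  ro_lif <- simulate_network(snn_network(w, p, kind = "lif"), x)
  expect_identical(ro_alif$z, ro_lif$z)
  expect_identical(ro_alif$v, ro_lif$v)
})

test_that("constant suprathreshold drive gives the ISI of the scalar recurrence", {
  p <- neuron_params(t_refrac = 3, beta_adapt = 0)
  w <- network_weights(1, 1, 1, seed = 1); w$W_rec[] <- 0
  net <- snn_network(w, p, kind = "lif")
  drive <- 0.4
  x <- array(drive / w$W_in[1, 1], c(1, 1, 60)) # constant current `drive`
  ro <- simulate_network(net, x)
  spikes <- which(ro$z[1, 1, ] == 1)
  # independent scalar unroll of the membrane recurrence
  v <- 0; z <- 0; refr <- 0; spikes_ref <- integer()
  for (t in 1:60) {
    v <- p$alpha * (v - p$v_th * z) + drive
    z <- as.numeric(v >= p$v_th && refr == 0)
    refr <- max(refr - 1, 0)
    if (z == 1) { spikes_ref <- c(spikes_ref, t); refr <- p$n_refrac }
  }
  expect_equal(spikes, spikes_ref)
  expect_true(all(diff(spikes) == diff(spikes)[1])) # regular ISI
})

test_that("identical simulate calls are bit-identical and NaNs are caught", {
  net <- toy_network(seed = 21)
  x <- random_input(2, 3, 40, seed = 3)
  ro1 <- simulate_network(net, x)
  ro2 <- simulate_network(net, x)
  expect_identical(ro1$z, ro2$z)
  expect_identical(ro1$y, ro2$y)
  bad <- net
  bad$weights$W_in[] <- NaN
  expect_error(simulate_network(bad, x), "numerical failure.*step 1")
})

test_that("mismatched shapes raise contract errors", {
  net <- toy_network()
  expect_error(simulate_network(net, array(0, c(1, 7, 10))), "channels")
  st <- neuron_state(1, 4, 1)
  w <- network_weights(3, 4, 2)
  expect_error(lif_step(st, matrix(0, 2, 4), neuron_params(), w,
                        matrix(0, 1, 4)), "shape mismatch")
})
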